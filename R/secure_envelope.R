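#' Generate an RSA key pair for envelope wrapping
#'
#' @param bits Modulus size (default 2048).
#' @return List with `private` (openssl RSA key) and `public` (its pubkey).
#' @export
rsa_keypair <- function(bits = 2048) {
  key <- openssl::rsa_keygen(bits)
  list(private = key, public = key$pubkey)
}

mac_key_for <- function(key) openssl::sha256(c(key, charToRaw("mac")))

#' Seal a record payload into a hybrid envelope
#'
#' Transport encryption: a fresh random 128-bit AES key per envelope
#' encrypts the payload (GCM mode), the key is wrapped with the
#' recipient's RSA public key (OAEP), and an HMAC-SHA256 over the IV and
#' ciphertext (encrypt-then-MAC) plus a SHA-256 digest of the plaintext
#' make tampering detectable rather than silently corrupting.
#'
#' @param plaintext Raw vector (non-empty) or a single string.
#' @param public_key Recipient RSA public key (from [rsa_keypair()]).
#' @param key_id Opaque identifier naming the recipient key (default "").
#' @return An `envelope` list: `ciphertext`, `iv`, `mac`, `wrapped_key`,
#'   `key_id`, `payload_digest` (all raw except `key_id`).
#' @export
seal_envelope <- function(plaintext, public_key, key_id = "") {
  if (is.character(plaintext) && length(plaintext) == 1L)
    plaintext <- charToRaw(plaintext)
  if (!is.raw(plaintext) || length(plaintext) == 0L)
    stop("plaintext must be a non-empty raw vector or single string")
  key <- openssl::rand_bytes(16L)  # 128-bit transport key, fresh per envelope
  iv <- openssl::rand_bytes(12L)
  ct <- openssl::aes_gcm_encrypt(plaintext, key, iv)
  attributes(ct) <- NULL
  env <- structure(list(
    ciphertext = ct, iv = iv,
    mac = openssl::sha256(c(iv, ct), key = mac_key_for(key)),
    wrapped_key = openssl::rsa_encrypt(key, public_key),
    key_id = as.character(key_id),
    payload_digest = openssl::sha256(plaintext)), class = "envelope")
  env
}

#' Open a hybrid envelope
#'
#' Unwraps the 128-bit transport key with the recipient's RSA private key,
#' verifies the HMAC before decrypting (tampered ciphertext fails loudly),
#' decrypts, and checks the plaintext digest.
#'
#' @param envelope An [seal_envelope()] envelope.
#' @param private_key Recipient RSA private key.
#' @return The original plaintext as a raw vector.
#' @export
open_envelope <- function(envelope, private_key) {
  stopifnot(inherits(envelope, "envelope"))
  key <- tryCatch(openssl::rsa_decrypt(envelope$wrapped_key, private_key),
                  error = function(e)
                    stop("key unwrap failed (wrong private key?): ",
                         conditionMessage(e), call. = FALSE))
  if (length(key) != 16L)
    stop("key unwrap failed: unwrapped transport key is not 128-bit")
  mac <- openssl::sha256(c(envelope$iv, envelope$ciphertext),
                         key = mac_key_for(key))
  if (!identical(as.raw(mac), as.raw(envelope$mac)))
    stop("envelope integrity check failed: ciphertext or IV was tampered with")
  pt <- openssl::aes_gcm_decrypt(envelope$ciphertext, key, envelope$iv)
  if (!identical(as.raw(openssl::sha256(pt)),
                 as.raw(envelope$payload_digest)))
    stop("payload digest mismatch after decryption")
  pt
}

#' Re-encrypt a payload for storage at rest
#'
#' At-rest storage uses 256-bit AES in cipher-block-chaining mode with a
#' long-lived storage key, plus a SHA-256 payload digest so corruption is
#' detected on read. A fresh IV per call makes repeated encryptions of the
#' same payload distinct.
#'
#' @param plaintext Raw vector or single string.
#' @param storage_key Raw vector of exactly 32 bytes (256-bit).
#' @return A `stored_blob` list: `ciphertext`, `iv`, `payload_digest`.
#' @export
reencrypt_at_rest <- function(plaintext, storage_key) {
  if (is.character(plaintext) && length(plaintext) == 1L)
    plaintext <- charToRaw(plaintext)
  if (!is.raw(storage_key) || length(storage_key) != 32L)
    stop("storage key must be exactly 32 bytes (256-bit)")
  iv <- openssl::rand_bytes(16L)
  ct <- openssl::aes_cbc_encrypt(plaintext, storage_key, iv)
  attributes(ct) <- NULL
  structure(list(ciphertext = ct, iv = iv,
                 payload_digest = openssl::sha256(plaintext)),
            class = "stored_blob")
}

#' @rdname reencrypt_at_rest
#' @param blob A `stored_blob`.
#' @return `decrypt_at_rest`: the original plaintext raw vector.
#' @export
decrypt_at_rest <- function(blob, storage_key) {
  stopifnot(inherits(blob, "stored_blob"))
  if (!is.raw(storage_key) || length(storage_key) != 32L)
    stop("storage key must be exactly 32 bytes (256-bit)")
  pt <- openssl::aes_cbc_decrypt(blob$ciphertext, storage_key, blob$iv)
  if (!identical(as.raw(openssl::sha256(pt)), as.raw(blob$payload_digest)))
    stop("stored blob integrity check failed")
  pt
}

#' Serialize / parse an envelope as JSON
#'
#' Fields are base64-encoded; the JSON round-trips to an envelope that
#' opens to the identical plaintext.
#'
#' @param envelope An envelope.
#' @return `envelope_to_json`: a JSON string; `envelope_from_json`: an
#'   `envelope`.
#' @export
envelope_to_json <- function(envelope) {
  stopifnot(inherits(envelope, "envelope"))
  b64 <- function(x) openssl::base64_encode(as.raw(x))
  jsonlite::toJSON(list(
    key_id = envelope$key_id, iv = b64(envelope$iv),
    wrapped_key = b64(envelope$wrapped_key),
    ciphertext = b64(envelope$ciphertext), mac = b64(envelope$mac),
    digest = b64(envelope$payload_digest)), auto_unbox = TRUE)
}

#' @rdname envelope_to_json
#' @param json JSON string from `envelope_to_json`.
#' @export
envelope_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  structure(list(ciphertext = openssl::base64_decode(x$ciphertext),
                 iv = openssl::base64_decode(x$iv),
                 mac = openssl::base64_decode(x$mac),
                 wrapped_key = openssl::base64_decode(x$wrapped_key),
                 key_id = x$key_id,
                 payload_digest = openssl::base64_decode(x$digest)),
            class = "envelope")
}
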