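#' Robust log scaling of gradients
#'
#' Compresses gradient magnitudes elementwise by `R * log(|R| / q + 1)`
#' (natural log): sign-preserving, strictly monotone in `|R|`, and
#' sub-quadratic for large magnitudes, which keeps additive-mask noise growth
#' under control across repeated homomorphic operations.
#'
#' @param R Numeric gradient vector.
#' @param q Positive stability constant (default 1).
#' @return Scaled vector of the same length.
#' @export
robust_log_scale <- function(R, q = 1) {
  if (q <= 0) stop_arg("`q` must be positive")
  if (!all(is.finite(R))) stop_data("gradient contains non-finite values")
  R * log1p(abs(R) / q)
}

#' Invert robust log scaling
#'
#' Solves `x * log(x / q + 1) = |y|` for `x >= 0` by monotone bisection with
#' Newton refinement and restores the sign, so the server can recover
#' gradients after unmasking. `inverse_rls(robust_log_scale(x)) == x` to
#' within `1e-6` (interior tolerance `1e-9`).
#'
#' @param scaled Numeric vector of RLS outputs.
#' @param q Positive stability constant used in the forward map.
#' @param tol Absolute tolerance on the root (default `1e-12`).
#' @param max_iter Bisection iteration cap.
#' @return The recovered gradient vector.
#' @export
inverse_rls <- function(scaled, q = 1, tol = 1e-12, max_iter = 200) {
  if (q <= 0) stop_arg("`q` must be positive")
  a <- abs(scaled)
  f <- function(x) x * log1p(x / q)
  lo <- rep(0, length(a))
  hi <- pmax(a, q)
  it <- 0
  while (any(f(hi) < a)) {
    hi <- ifelse(f(hi) < a, hi * 2, hi)
    it <- it + 1
    if (it > 200) stop_numeric("inverse_rls: bracket expansion failed")
  }
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    below <- f(mid) < a
    lo <- ifelse(below, mid, lo)
    hi <- ifelse(below, hi, mid)
    if (max(hi - lo) < tol) break
  }
  x <- (lo + hi) / 2
  if (max(abs(f(x) - a)) > 1e-6 * (1 + max(a))) {
    stop_numeric("inverse_rls did not reach tolerance")
  }
  sign(scaled) * x
}

# SHA-256 counter-mode PRG emitting uniforms in [0, 1); 9 draws of 28 bits
# per digest call. Deterministic in the seed material string.
prg_uniform <- function(seed_material, n) {
  out <- numeric(0)
  block <- 0
  while (length(out) < n) {
    h <- sha256_hex(paste0(seed_material, "#", block))
    chunks <- substring(h, seq(1, 57, by = 7), seq(7, 63, by = 7))
    out <- c(out, strtoi(chunks, base = 16L) / 2^28)
    block <- block + 1
  }
  out[seq_len(n)]
}

#' Generate an additive-masking key pair
#'
#' Derives the secret mask seed `phi` and the public noise parameters
#' `(d, e)` from a master seed via a SHA-256 PRG; deterministic per seed.
#' The public part never contains bytes of `phi` (only a one-way key id).
#'
#' @param master_seed Integer or string master seed.
#' @param mask_width_factor Mask half-width as a multiple of the plaintext
#'   RMS (default 1000): large enough to hide magnitudes, small enough that
#'   unmasking stays exact to float tolerance.
#' @return An object of class `hrlse_keys` with `public` (scheme, key id,
#'   noise parameters) and `private` (`phi`); used nonces are tracked.
#' @export
hrlse_keygen <- function(master_seed, mask_width_factor = 1000) {
  phi <- sha256_hex(paste0("hrlse-phi|", master_seed))
  d <- sha256_hex(paste0("hrlse-d|", master_seed))
  e <- sha256_hex(paste0("hrlse-e|", master_seed))
  key_id <- sha256_hex(paste0("hrlse-kid|", phi))
  used <- new.env(parent = emptyenv())
  structure(
    list(
      public = list(scheme = "additive-mask-v1", key_id = key_id,
                    noise = list(d = d, e = e),
                    mask_width_factor = mask_width_factor),
      private = list(phi = phi),
      used_nonces = used
    ),
    class = "hrlse_keys"
  )
}

mask_for <- function(keys, nonce, n, scale) {
  u <- prg_uniform(paste0(keys$private$phi, "|", nonce), n)
  (2 * u - 1) * scale
}

#' Mask (encrypt) a scaled gradient
#'
#' Adds a seed-derived pseudorandom mask, uniform on `(-w, w)` with
#' `w = mask_width_factor * RMS(x)`, to the plaintext. Masking is additively
#' homomorphic: ciphertexts can be summed coordinate-wise and the sum
#' unmasked with the masks of all contributing nonces. Each nonce may be
#' used once per key; reuse raises a security error.
#'
#' @param x Numeric plaintext vector (normally the RLS-scaled gradient).
#' @param keys An [hrlse_keygen()] key pair.
#' @param nonce Unique string nonce for this encryption.
#' @param rls_applied Flag recorded on the record (default `TRUE`).
#' @return An object of class `cipher_gradient`: `values`, `key_id`,
#'   `nonces`, `mask_scales`, `length`, `rls` flag.
#' @export
hrlse_encrypt <- function(x, keys, nonce, rls_applied = TRUE) {
  stopifnot(inherits(keys, "hrlse_keys"))
  nonce <- as.character(nonce)
  if (exists(nonce, envir = keys$used_nonces, inherits = FALSE)) {
    stop_security(paste0("nonce reuse detected: `", nonce, "`"))
  }
  assign(nonce, TRUE, envir = keys$used_nonces)
  rms <- sqrt(mean(x^2))
  scale <- keys$public$mask_width_factor * (if (rms > 0) rms else 1)
  structure(
    list(values = x + mask_for(keys, nonce, length(x), scale),
         key_id = keys$public$key_id,
         nonces = nonce, mask_scales = scale,
         length = length(x), rls = rls_applied),
    class = "cipher_gradient"
  )
}

#' Add two ciphertexts coordinate-wise
#'
#' @param c1,c2 `cipher_gradient` records under the same key and length.
#' @return A combined `cipher_gradient` carrying both nonce histories.
#' @export
cipher_add <- function(c1, c2) {
  if (c1$key_id != c2$key_id) stop_key("ciphertexts under different keys")
  if (c1$length != c2$length) stop_data("ciphertext length mismatch")
  structure(
    list(values = c1$values + c2$values, key_id = c1$key_id,
         nonces = c(c1$nonces, c2$nonces),
         mask_scales = c(c1$mask_scales, c2$mask_scales),
         length = c1$length, rls = c1$rls && c2$rls),
    class = "cipher_gradient"
  )
}

#' Unmask (decrypt) a ciphertext
#'
#' Subtracts the PRG masks of every nonce recorded on the ciphertext;
#' for a sum of ciphertexts this recovers the sum of plaintexts.
#'
#' @param cipher A `cipher_gradient`.
#' @param keys The matching [hrlse_keygen()] key pair.
#' @return The plaintext vector.
#' @export
hrlse_decrypt <- function(cipher, keys) {
  stopifnot(inherits(keys, "hrlse_keys"))
  if (cipher$key_id != keys$public$key_id) {
    stop_key("unknown key id for this ciphertext")
  }
  x <- cipher$values
  for (i in seq_along(cipher$nonces)) {
    x <- x - mask_for(keys, cipher$nonces[i], cipher$length,
                      cipher$mask_scales[i])
  }
  x
}

#' Protect and recover a gradient end to end
#'
#' `protect_gradient` applies robust log scaling then masking;
#' `recover_gradient` unmasks then inverts the scaling.
#'
#' @param R Plain gradient vector.
#' @param keys An [hrlse_keygen()] key pair.
#' @param nonce Unique nonce.
#' @param q RLS stability constant.
#' @return `protect_gradient`: a `cipher_gradient`; `recover_gradient`: the
#'   original gradient (to `1e-6`).
#' @export
protect_gradient <- function(R, keys, nonce, q = 1) {
  hrlse_encrypt(robust_log_scale(R, q), keys, nonce, rls_applied = TRUE)
}

#' @rdname protect_gradient
#' @param cipher A `cipher_gradient` from [protect_gradient()].
#' @export
recover_gradient <- function(cipher, keys, q = 1) {
  inverse_rls(hrlse_decrypt(cipher, keys), q)
}
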