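# Big-integer byte encoding of a string reduced mod p, by Horner in base 256.
# With p <= 2^31 - 1 every intermediate stays below 2^39, exact in doubles.
int_mod <- function(s, p) {
  bytes <- as.integer(charToRaw(s))
  acc <- 0
  for (b in bytes) acc <- (acc * 256 + b) %% p
  acc
}

default_prime <- function() 2147483647  # 2^31 - 1, Mersenne prime

#' Exponential-probing hash of a hospital identity
#'
#' `gamma = u + exp(int(T) mod p)` at fixed precision, where `int(T)` is the
#' big-integer byte encoding of the id. The exponential is evaluated on the
#' residue reduced mod 16 so that, at the fixed-point scale, every quantity
#' is an exact integer count of `1/scale` units and later signature
#' comparison is exact equality, never a float comparison.
#'
#' @param T Nonempty hospital id string.
#' @param u Additive constant (default 1).
#' @param p Prime modulus (default `2^31 - 1`).
#' @param scale Fixed-precision scale, a positive power of ten (default
#'   `1e6`).
#' @return The hash value; attribute `"micro"` holds the exact integer count
#'   of `1/scale` units.
#' @export
expr_hash <- function(T, u = 1, p = default_prime(), scale = 1e6) {
  if (!is.character(T) || length(T) != 1 || nchar(T) == 0) {
    stop_arg("`T` must be a nonempty string")
  }
  if (p < 2) stop_arg("`p` must be a prime >= 2")
  if (scale <= 0 || log10(scale) %% 1 != 0) {
    stop_arg("`scale` must be a positive power of ten")
  }
  r <- int_mod(T, p)
  micro <- round(u * scale) + round(exp(r %% 16) * scale)
  structure(micro / scale, micro = micro, residue = r)
}

# Canonical fixed-precision numeric encoding of an arbitrary object: the
# byte encoding of its canonical JSON, reduced mod p.
numeric_encode <- function(x, p) {
  if (is.character(x) && length(x) == 1) int_mod(x, p) else
    int_mod(canonical_json(x), p)
}

#' Create a digital signature for a hospital submission
#'
#' `D = numeric(T) + gamma + numeric(eps)` at fixed precision, where
#' `numeric(.)` is the canonical big-integer encoding reduced mod `p`.
#' Bit-exactly reproducible from `(T, eps, u, p, scale)`.
#'
#' @param T Hospital id string.
#' @param public_key The hospital's public key (any serializable object; the
#'   `public` element of [hrlse_keygen()] in the full pipeline).
#' @param u,p,scale Session constants shared with [expr_hash()].
#' @return An object of class `signature_record` with `gamma`, `D`, the
#'   session constants, and exact `*_micro` integer forms.
#' @export
dsa_sign <- function(T, public_key, u = 1, p = default_prime(), scale = 1e6) {
  gamma <- expr_hash(T, u, p, scale)
  t_micro <- numeric_encode(T, p) * scale
  e_micro <- numeric_encode(public_key, p) * scale
  d_micro <- t_micro + attr(gamma, "micro") + e_micro
  structure(
    list(id = T, gamma = as.numeric(gamma),
         gamma_micro = attr(gamma, "micro"),
         D = d_micro / scale, D_micro = d_micro,
         u = u, p = p, scale = scale),
    class = "signature_record"
  )
}

#' Hospital registry
#'
#' Server-side store of registered identities: salted password digests and
#' public keys. Passwords are never stored in clear; the salt is derived
#' deterministically from the registry's salt seed so simulations are
#' reproducible.
#'
#' @param salt_seed Seed material for per-id salts.
#' @return An object of class `hospital_registry` (environment-backed).
#' @export
hospital_registry <- function(salt_seed = "fedcep-registry") {
  structure(list(store = new.env(parent = emptyenv()),
                 salt_seed = salt_seed),
            class = "hospital_registry")
}

#' Register and authenticate hospital identities
#'
#' `register_hospital` stores the salted password digest and public key;
#' `login_hospital` checks the digest. Both are recorded on the ledger by
#' the federation driver.
#'
#' @param registry A [hospital_registry()].
#' @param id Unique nonempty hospital id.
#' @param password Password string.
#' @param public_key The hospital's public key object.
#' @return `register_hospital`: the registry, invisibly; `login_hospital`:
#'   `TRUE`/`FALSE`.
#' @export
register_hospital <- function(registry, id, password, public_key) {
  if (nchar(id) == 0) stop_arg("empty hospital id")
  if (exists(id, envir = registry$store, inherits = FALSE)) {
    stop_arg(paste0("hospital id `", id, "` already registered"))
  }
  salt <- sha256_hex(paste0(registry$salt_seed, "|", id))
  assign(id,
         list(salt = salt,
              pw_digest = sha256_hex(paste0(salt, "|", password)),
              public_key = public_key),
         envir = registry$store)
  invisible(registry)
}

#' @rdname register_hospital
#' @export
login_hospital <- function(registry, id, password) {
  if (!exists(id, envir = registry$store, inherits = FALSE)) return(FALSE)
  rec <- get(id, envir = registry$store)
  identical(rec$pw_digest, sha256_hex(paste0(rec$salt, "|", password)))
}

#' Verify a submitted signature on the server side
#'
#' The server recomputes the exponential-probing hash and the signature from
#' the claimed id and the public key it holds from registration, and accepts
#' (`J1`) iff the recomputed signature equals the submitted one exactly (at
#' fixed precision). Any mismatch, or an unregistered id, yields `J2`, which
#' blocks the gradient transmission.
#'
#' @param registry A [hospital_registry()].
#' @param record A [dsa_sign()] `signature_record` submitted by the client.
#' @param claimed_id The id the client claims.
#' @return List with `result` (`"J1"` or `"J2"`) and `reason`.
#' @export
dsa_verify <- function(registry, record, claimed_id) {
  if (!exists(claimed_id, envir = registry$store, inherits = FALSE)) {
    return(list(result = "J2", reason = "unregistered"))
  }
  stored <- get(claimed_id, envir = registry$store)
  server <- dsa_sign(claimed_id, stored$public_key,
                     u = record$u, p = record$p, scale = record$scale)
  if (identical(server$D_micro, record$D_micro)) {
    list(result = "J1", reason = "signature match")
  } else {
    list(result = "J2", reason = "signature mismatch")
  }
}
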