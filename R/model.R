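#' Define a flexible-semiflexible multiblock copolymer model
#'
#' Builds the parameter set for a single chain of `N` hard-sphere beads
#' (diameter `sigma`) connected by free bonds of length `l_min`..`l_max`, with
#' two bead types (S = semiflexible, F = flexible) alternating in blocks of
#' length `b`.  Non-bonded beads within `R_cut` of each other contribute a
#' square-well contact energy (`eps_ss`, `eps_ff`, `eps_sf`); valence angles
#' inside the window `[theta_min, theta_max]` whose three beads all belong to
#' one S block contribute the stiffness energy `eps_st` each.
#'
#' Two selective-solvent presets are provided.  `"S-attract"` uses
#' (eps_ss, eps_sf, eps_ff) = (-4, -2, -1).  `"F-attract"` uses physical
#' energies (-0.25, -0.5, -1); internally the integer values (-1, -2, -4)
#' are stored and rescaled by `raw_scale = 0.25`, so that the non-valent
#' energy coordinate of a macrostate stays an exact integer.
#' `"non-selective"` sets all three to -1.
#'
#' @param N chain length (beads).
#' @param b block length (beads per block).  `N` must be divisible by `2 * b`
#'   unless an explicit `pattern` is supplied.
#' @param preset solvent preset: `"S-attract"`, `"F-attract"` or
#'   `"non-selective"` (the `-stronger` suffixed spellings are accepted).
#'   Ignored when `eps` is given.
#' @param eps optional named numeric vector `c(ss=, ff=, sf=)` of physical
#'   contact energies (each <= 0); `eps / raw_scale` must be integers.
#' @param raw_scale multiplicative factor converting stored integer contact
#'   energies to physical units.
#' @param eps_st stiffness energy per favorable angle (<= 0).
#' @param pattern optional explicit bead-type pattern, a character vector of
#'   `"S"`/`"F"` of length `N` (overrides `b`-block layout; the equal
#'   composition invariant is then not enforced).
#' @param start_type type of the first block, `"S"` (default) or `"F"`.
#' @param phantom logical; if `TRUE` the hard-sphere and contact terms are
#'   disabled (ideal phantom chain, used by the oracles).
#' @param lorentz_berthelot logical; when `TRUE`, require
#'   `|eps_sf| = sqrt(|eps_ss| * |eps_ff|)`.
#' @param l_min,l_max bond-length bounds (units of `sigma`).
#' @param sigma hard-sphere diameter (the length unit).
#' @param R_cut square-well contact cutoff.
#' @param theta_min,theta_max favorable valence-angle window (degrees).
#' @param k_max maximum regrown segment length of the end-cut-and-regrow
#'   move; defaults to `b` (one block).
#' @param move_delta half width of the per-axis local displacement.
#' @return an object of class `sf_model`.
#' @examples
#' m <- sf_model(N = 16, b = 4, preset = "S-attract", eps_st = -2)
#' m$eps_ss
#' @export
sf_model <- function(N = 64L, b = 4L,
                     preset = c("S-attract", "F-attract", "non-selective",
                                "S-attract-stronger", "F-attract-stronger"),
                     eps = NULL, raw_scale = NULL, eps_st = 0,
                     pattern = NULL, start_type = c("S", "F"),
                     phantom = FALSE, lorentz_berthelot = TRUE,
                     l_min = 0.8, l_max = 1.25, sigma = 1.0, R_cut = 1.5,
                     theta_min = 150, theta_max = 170,
                     k_max = NULL, move_delta = 0.05) {
  N <- as.integer(N)
  b <- as.integer(b)
  start_type <- match.arg(start_type)
  preset <- match.arg(preset)
  preset <- sub("-stronger$", "", preset)

  if (!(sigma > 0)) stop("sigma must be positive")
  if (!(l_min > 0 && l_min < l_max))
    stop("bond bounds must satisfy 0 < l_min < l_max")
  if (!(l_max < sqrt(2) * sigma))
    stop("l_max must be < sqrt(2)*sigma so that bonds cannot cross")
  if (!(theta_min > 0 && theta_min < theta_max && theta_max < 180))
    stop("angle window must satisfy 0 < theta_min < theta_max < 180")
  if (eps_st > 0) stop("eps_st must be <= 0")

  if (is.null(pattern)) {
    if (N < 2L) stop("N must be at least 2")
    if (N %% (2L * b) != 0L)
      stop("N must be divisible by 2*b (equal numbers of S and F blocks)")
    pattern <- block_pattern(N, b, start_type)
  } else {
    pattern <- as.character(pattern)
    if (length(pattern) != N) stop("pattern must have length N")
    if (!all(pattern %in% c("S", "F"))) stop("pattern entries must be 'S' or 'F'")
  }

  if (is.null(eps)) {
    tab <- switch(preset,
      "S-attract"     = list(phys = c(ss = -4,    ff = -1, sf = -2),
                             raw  = c(ss = -4L, ff = -1L, sf = -2L), scale = 1),
      "F-attract"     = list(phys = c(ss = -0.25, ff = -1, sf = -0.5),
                             raw  = c(ss = -1L, ff = -4L, sf = -2L), scale = 0.25),
      "non-selective" = list(phys = c(ss = -1,    ff = -1, sf = -1),
                             raw  = c(ss = -1L, ff = -1L, sf = -1L), scale = 1))
    eps_phys <- tab$phys
    eps_raw <- tab$raw
    raw_scale <- tab$scale
  } else {
    if (is.null(raw_scale)) raw_scale <- 1
    eps <- eps[c("ss", "ff", "sf")]
    if (anyNA(eps)) stop("eps must be a named vector with entries ss, ff, sf")
    if (any(eps > 0)) stop("contact energies must be <= 0 (attractive or zero)")
    raw <- eps / raw_scale
    if (any(abs(raw - round(raw)) > 1e-9))
      stop("eps / raw_scale must be integers (exact macrostate bookkeeping)")
    eps_phys <- eps
    eps_raw <- as.integer(round(raw))
    names(eps_raw) <- c("ss", "ff", "sf")
  }
  if (lorentz_berthelot && !phantom) {
    lb <- sqrt(abs(eps_phys[["ss"]]) * abs(eps_phys[["ff"]]))
    if (abs(abs(eps_phys[["sf"]]) - lb) > 1e-9)
      stop(sprintf(
        "Lorentz-Berthelot violation: |eps_sf| = %g but sqrt(|ss||ff|) = %g",
        abs(eps_phys[["sf"]]), lb))
  }
  if (phantom) {
    eps_phys[] <- 0
    eps_raw[] <- 0L
  }
  if (is.null(k_max)) k_max <- min(b, N - 1L)

  types <- as.integer(pattern == "S")
  m <- structure(list(
    N = N, b = b, preset = preset,
    sigma = sigma, l_min = l_min, l_max = l_max, R_cut = R_cut,
    theta_min = theta_min, theta_max = theta_max,
    eps_ss = eps_phys[["ss"]], eps_ff = eps_phys[["ff"]],
    eps_sf = eps_phys[["sf"]],
    eps_raw = unname(eps_raw), raw_scale = raw_scale, eps_st = eps_st,
    pattern = pattern, types = types, phantom = phantom,
    k_max = as.integer(k_max), move_delta = move_delta
  ), class = "sf_model")
  m
}

#' Bead-type pattern of a regular multiblock chain
#'
#' @param N chain length; must be divisible by `2 * b`.
#' @param b block length.
#' @param start_type type of the first block.
#' @return character vector of `"S"`/`"F"` of length `N`.
#' @export
block_pattern <- function(N, b, start_type = "S") {
  N <- as.integer(N); b <- as.integer(b)
  if (N %% (2L * b) != 0L) stop("N must be divisible by 2*b")
  first <- if (start_type == "S") c("S", "F") else c("F", "S")
  rep(rep(first, N / (2L * b)), each = b)
}

#' Maximum attainable number of favorable stiff angles
#'
#' An angle is eligible only when all three beads of its triplet are S-type,
#' so each S block of length `b` contributes at most `b - 2` angles.
#'
#' @param model an `sf_model`.
#' @return integer.
#' @export
nst_max <- function(model) {
  t <- model$types
  n <- length(t)
  if (n < 3) return(0L)
  sum(t[1:(n - 2)] & t[2:(n - 1)] & t[3:n])
}

#' @export
print.sf_model <- function(x, ...) {
  cat(sprintf("<sf_model> N=%d b=%d preset=%s%s\n", x$N, x$b, x$preset,
              if (x$phantom) " (phantom)" else ""))
  cat(sprintf("  eps (ss, ff, sf) = (%g, %g, %g), raw (%d, %d, %d) x %g\n",
              x$eps_ss, x$eps_ff, x$eps_sf,
              x$eps_raw[1], x$eps_raw[2], x$eps_raw[3], x$raw_scale))
  cat(sprintf("  eps_st = %g, bonds [%g, %g], Rcut = %g, theta [%g, %g] deg\n",
              x$eps_st, x$l_min, x$l_max, x$R_cut, x$theta_min, x$theta_max))
  cat(sprintf("  pattern: %s\n", paste(x$pattern, collapse = "")))
  invisible(x)
}

# plain list for the C++ core
model_cpp <- function(model) {
  list(N = model$N, types = model$types, sigma = model$sigma,
       l_min = model$l_min, l_max = model$l_max, R_cut = model$R_cut,
       theta_min = model$theta_min, theta_max = model$theta_max,
       move_delta = model$move_delta, k_max = model$k_max,
       eps_raw = model$eps_raw, phantom = model$phantom)
}

#' Fingerprint of a model parameter set
#'
#' MD5 hash of the canonical JSON serialization of every parameter that
#' affects sampling; used to guard against mixing artifacts from different
#' models.
#'
#' @param model an `sf_model`.
#' @return a character scalar.
#' @export
model_fingerprint <- function(model) {
  key <- model[c("N", "b", "sigma", "l_min", "l_max", "R_cut", "theta_min",
                 "theta_max", "eps_raw", "raw_scale", "pattern", "phantom",
                 "k_max", "move_delta")]
  js <- jsonlite::toJSON(key, auto_unbox = TRUE, digits = NA)
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(js, tf)
  unname(tools::md5sum(tf))
}

#' Slightly perturbed straight-chain starting conformation
#'
#' Beads are placed along the x axis with bond length 1.0 and a small
#' transverse jitter drawn from the current RNG stream (so a preceding
#' `set.seed()` call makes it reproducible).  The result is always valid:
#' bonds stay inside `[l_min, l_max]` and non-bonded beads are at least
#' `2 * sigma` apart.
#'
#' @param model an `sf_model`.
#' @param jitter transverse jitter amplitude.
#' @return an `N x 3` coordinate matrix.
#' @export
initial_conformation <- function(model, jitter = 0.01) {
  N <- model$N
  coords <- cbind(seq_len(N) - 1,
                  runif(N, -jitter, jitter),
                  runif(N, -jitter, jitter))
  v <- validate_conformation(coords, model)
  if (!v$valid) stop("internal error: initial conformation invalid")
  coords
}

#' Validate a conformation against the model geometry
#'
#' A conformation is valid when every bond length lies in
#' `[l_min, l_max]` and every non-bonded pair is at least `sigma` apart
#' (bonded beads may interpenetrate; for phantom models the hard-sphere
#' check is skipped).
#'
#' @param coords `N x 3` coordinate matrix.
#' @param model an `sf_model`.
#' @return list with `valid` (logical) and, when invalid, `violation`
#'   (a human-readable description of the first violation found).
#' @export
validate_conformation <- function(coords, model) {
  coords <- check_coords(coords, model)
  r <- cc_validate(coords, model_cpp(model))
  violation <- NULL
  if (!r$valid)
    violation <- if (r$kind == 1)
      sprintf("bond %d-%d outside [l_min, l_max]", r$where, r$where + 1)
    else
      sprintf("hard-sphere overlap involving bead %d", r$where)
  list(valid = r$valid, violation = violation)
}

check_coords <- function(coords, model) {
  coords <- as.matrix(coords)
  if (nrow(coords) != model$N || ncol(coords) != 3)
    stop("coords must be an N x 3 matrix")
  if (!all(is.finite(coords))) stop("coords contain non-finite values")
  storage.mode(coords) <- "double"
  coords
}

#' Count contacts and favorable stiff angles
#'
#' `nss`, `nff` and `nsf` count unordered non-bonded bead pairs (chain
#' distance of at least 2) within `R_cut` of each other, split by type pair;
#' `nst` counts valence angles inside `[theta_min, theta_max]` whose triplet
#' is entirely S-type.
#'
#' @inheritParams validate_conformation
#' @return list with integer fields `nss`, `nff`, `nsf`, `nst`.
#' @export
count_contacts <- function(coords, model) {
  coords <- check_coords(coords, model)
  r <- cc_count_contacts(coords, model_cpp(model))
  r[c("nss", "nff", "nsf", "nst")]
}

#' Energy breakdown of a conformation or of contact counts
#'
#' Computes the non-valent energy `Env = eps_ss*nss + eps_ff*nff +
#' eps_sf*nsf`, the stiffness energy `Est = eps_st * nst`, and the total
#' conformational energy `U = Env + Est`.  `Env_raw` is the integer contact
#' energy in raw units, with `Env = raw_scale * Env_raw`.
#'
#' @param x either a contact-count list (fields `nss`, `nff`, `nsf`, `nst`)
#'   or an `N x 3` coordinate matrix.
#' @param model an `sf_model`.
#' @return list with `Env_raw`, `Env`, `Est`, `U`.
#' @export
chain_energy <- function(x, model) {
  counts <- if (is.matrix(x)) count_contacts(x, model) else x
  er <- model$eps_raw
  env_raw <- er[1] * counts$nss + er[2] * counts$nff + er[3] * counts$nsf
  env <- model$raw_scale * env_raw
  est <- model$eps_st * counts$nst
  list(Env_raw = as.integer(env_raw), Env = env, Est = est, U = env + est)
}

#' Macrostate coordinates of a conformation
#'
#' @inheritParams validate_conformation
#' @return list with integer `Env_raw` and `nst`.
#' @export
macrostate <- function(coords, model) {
  coords <- check_coords(coords, model)
  r <- cc_count_contacts(coords, model_cpp(model))
  list(Env_raw = r$Env_raw, nst = r$nst)
}

#' Propose a local displacement move
#'
#' One uniformly chosen bead is displaced by independent uniform offsets in
#' `[-move_delta, move_delta]` along each axis.  The proposal density is
#' symmetric; geometric invalidity of the candidate is reported, not raised.
#'
#' @inheritParams validate_conformation
#' @return list with `coords` (candidate), `bead` (1-based index of the moved
#'   bead) and `valid`.
#' @export
propose_local_move <- function(coords, model) {
  coords <- check_coords(coords, model)
  cc_propose_local(coords, model_cpp(model))
}

#' Propose an end-cut-and-regrow move
#'
#' A chain end and a cut length `k` (uniform on `1..k_max`) are chosen; the
#' `k` terminal beads are re-placed sequentially, each new bond vector drawn
#' uniformly with respect to volume from the spherical shell
#' `l_min <= |v| <= l_max`.  The proposal density is symmetric under this
#' measure.
#'
#' @inheritParams validate_conformation
#' @return list with `coords`, `k`, `end` (`"head"` or `"tail"`) and `valid`.
#' @export
propose_end_regrow <- function(coords, model) {
  coords <- check_coords(coords, model)
  cc_propose_regrow(coords, model_cpp(model))
}
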