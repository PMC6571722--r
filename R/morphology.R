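# Morphology observables and the hierarchical classifier.
#
# Five criteria drive the taxonomy: (i) squared gyration radii of the whole
# chain and of each bead type, (ii) contact numbers (liquid vs frozen
# packing), (iii) gyration-tensor shape parameters (sphere / prolate /
# oblate), (iv) nematic bond order of the S blocks (isotropic vs
# liquid-crystalline), (v) S/F demixing and shell adsorption.

#' Morphology feature vector of a conformation
#'
#' Pure-R reference implementation (the compiled production loop computes
#' the same quantities; the two are cross-checked in the test suite).
#' Features: squared gyration radii and gyration-tensor eigenvalues for the
#' whole chain and for the S and F subsets, asphericity and prolateness per
#' subset, nematic order of S-block bonds, contact counts, per-S-block
#' end-to-end extension ratio, sharp-fold count, and the demixing ratio
#' `nsf / (nss + nff + nsf)`.
#'
#' @inheritParams validate_conformation
#' @return a one-row data.frame of class `sf_features`.
#' @export
morphology_features <- function(coords, model) {
  coords <- check_coords(coords, model)
  cn <- count_contacts(coords, model)
  s_idx <- which(model$types == 1L)
  f_idx <- which(model$types == 0L)
  gyr <- function(idx) {
    if (length(idx) == 0) return(list(rg2 = 0, lam = c(0, 0, 0)))
    x <- coords[idx, , drop = FALSE]
    x <- sweep(x, 2, colMeans(x))
    g <- crossprod(x) / nrow(x)
    lam <- sort(eigen(g, symmetric = TRUE, only.values = TRUE)$values,
                decreasing = TRUE)
    list(rg2 = sum(diag(g)), lam = lam)
  }
  ga <- gyr(seq_len(model$N)); gs <- gyr(s_idx); gf <- gyr(f_idx)
  # bond-orientation order of S-block bonds: nematic (largest eigenvalue
  # of the traceless tensor Q) and planar (minus its smallest eigenvalue,
  # large when bonds are confined to a plane, as in toroids)
  sb <- which(model$types[-model$N] == 1L & model$types[-1] == 1L)
  s_nem <- 0
  s_planar <- 0
  if (length(sb)) {
    u <- coords[sb + 1, , drop = FALSE] - coords[sb, , drop = FALSE]
    u <- u / sqrt(rowSums(u^2))
    Q <- (3 * crossprod(u) / nrow(u) - diag(3)) / 2
    ev <- eigen(Q, symmetric = TRUE, only.values = TRUE)$values
    s_nem <- max(ev)
    s_planar <- -min(ev)
  }
  # per-S-block end-to-end / contour ratio
  runs <- rle(model$types)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  ext <- numeric(0)
  for (i in which(runs$values == 1L & runs$lengths >= 2L)) {
    a <- starts[i]; b <- ends[i]
    ete <- sqrt(sum((coords[b, ] - coords[a, ])^2))
    cont <- sum(sqrt(rowSums((coords[(a + 1):b, , drop = FALSE] -
                              coords[a:(b - 1), , drop = FALSE])^2)))
    ext <- c(ext, ete / cont)
  }
  # sharp folds: eligible all-S angles with theta < 90 degrees
  folds <- 0L
  if (model$N >= 3)
    for (ctr in 2:(model$N - 1)) {
      if (!(model$types[ctr - 1] && model$types[ctr] && model$types[ctr + 1]))
        next
      a <- coords[ctr - 1, ] - coords[ctr, ]
      b <- coords[ctr + 1, ] - coords[ctr, ]
      if (sum(a * b) > 0) folds <- folds + 1L
    }
  tot <- cn$nss + cn$nff + cn$nsf
  shape <- function(lam) {
    tr <- sum(lam)
    asph <- lam[1] - (lam[2] + lam[3]) / 2
    prol <- if (tr > 0)
      prod(3 * lam - tr) / tr^3 else 0
    c(asph = asph, prol = prol)
  }
  sa <- shape(ga$lam); ss <- shape(gs$lam); sf <- shape(gf$lam)
  structure(data.frame(
    rg2_all = ga$rg2, rg2_S = gs$rg2, rg2_F = gf$rg2,
    lam1_all = ga$lam[1], lam2_all = ga$lam[2], lam3_all = ga$lam[3],
    lam1_S = gs$lam[1], lam2_S = gs$lam[2], lam3_S = gs$lam[3],
    lam1_F = gf$lam[1], lam2_F = gf$lam[2], lam3_F = gf$lam[3],
    asph_all = sa["asph"], prol_all = sa["prol"],
    asph_S = ss["asph"], prol_S = ss["prol"],
    asph_F = sf["asph"], prol_F = sf["prol"],
    s_nem = s_nem, s_planar = s_planar,
    nss = cn$nss, nff = cn$nff, nsf = cn$nsf,
    ext_S = if (length(ext)) mean(ext) else 0,
    n_folds = folds,
    demix = if (tot > 0) cn$nsf / tot else 0,
    row.names = NULL), class = c("sf_features", "data.frame"))
}

#' Classifier thresholds
#'
#' The taxonomy thresholds are not universal constants: they were calibrated
#' on this package's own small-chain production runs and are expressed in
#' scale-free form where possible (gyration radii relative to the
#' freely-jointed reference `n l^2 / 6` for the relevant subset; contacts
#' per bead).  Every label returned by [classify_morphology()] carries the
#' full rule trace so users can audit and recalibrate.
#'
#' @param coil_frac a subset counts as coil-like when its `Rg^2` is at least
#'   this fraction of the freely-jointed reference.
#' @param collapse_frac a subset counts as collapsed below this fraction.
#' @param frozen_contacts contacts per bead at and above which a globule is
#'   frozen (solid) rather than liquid.
#' @param nematic_cut S-bond nematic order above which a globule is
#'   anisotropic (liquid-crystalline).
#' @param planar_cut S-bond planar order (minus the smallest eigenvalue of
#'   the orientation tensor) above which a globule counts as anisotropic;
#'   captures toroidal winding that the nematic eigenvalue misses.
#' @param ext_cut per-block extension ratio above which S blocks count as
#'   extended.
#' @param oblate_cut,prolate_cut prolateness thresholds for oblate / prolate
#'   shape of the S subset.
#' @param hole_radius toroid hole test: no S bead within this radius of the
#'   S centroid.
#' @param adsorb_contacts S-F contacts per F bead below which the F shell
#'   counts as loose (primed label).
#' @param schema_version identifier written with serialized thresholds.
#' @return list of class `sf_thresholds`.
#' @export
sf_thresholds <- function(coil_frac = 0.75, collapse_frac = 0.6,
                          frozen_contacts = 7, nematic_cut = 0.6,
                          planar_cut = 0.4, ext_cut = 0.9,
                          oblate_cut = -0.05, prolate_cut = 0.05,
                          hole_radius = 0.75, adsorb_contacts = 1.0,
                          schema_version = "1") {
  structure(as.list(environment()), class = "sf_thresholds")
}

rg2_ref <- function(n, l = 1) n * l^2 / 6

#' Hierarchical morphology classification
#'
#' Assigns one label of the taxonomy `Ia, Ib, IIa, IIb, IIc, IIIa, IIIb,
#' IIIc, IIId, IIIe, IIIe'` from a feature vector:
#' coils (I) vs globules by gyration radii, Ia/Ib by S-block extension,
#' flower/tadpole globules (IIc) when only the F blocks are collapsed,
#' liquid/frozen (IIa/IIb) by contact count, isotropic vs anisotropic by
#' S-bond nematic order, and anisotropic sub-labels by shape, folds, toroid
#' hole test and F-shell adsorption.
#'
#' @param features one-row `sf_features` data.frame (or per-macrostate
#'   means with the same columns).
#' @param model the `sf_model` the features were computed under.
#' @param thresholds an [sf_thresholds()] object.
#' @param coords optional conformation used for the toroid hole test; when
#'   absent the hole test falls back to the oblate-shape criterion alone.
#' @return list with `label` and `trace` (character vector of fired rules).
#' @export
classify_morphology <- function(features, model,
                                thresholds = sf_thresholds(),
                                coords = NULL) {
  f <- as.list(features)
  th <- thresholds
  if (!all(is.finite(unlist(f[c("rg2_all", "rg2_S", "rg2_F", "s_nem")]))))
    stop("features must be finite")
  trace <- character(0)
  note <- function(...) trace <<- c(trace, sprintf(...))
  n <- model$N
  n_s <- sum(model$types == 1L)
  n_f <- n - n_s

  ref_all <- rg2_ref(n); ref_s <- rg2_ref(n_s); ref_f <- rg2_ref(n_f)
  f_collapsed <- f$rg2_F < th$collapse_frac * ref_f
  s_collapsed <- f$rg2_S < th$collapse_frac * ref_s
  all_coil <- f$rg2_all >= th$coil_frac * ref_all
  note("rg2_all=%.3g vs coil cut %.3g", f$rg2_all, th$coil_frac * ref_all)
  note("rg2_F=%.3g vs collapse cut %.3g", f$rg2_F, th$collapse_frac * ref_f)
  contacts_per_bead <- 2 * (f$nss + f$nff + f$nsf) / n
  s_extended <- f$ext_S > th$ext_cut

  if (!f_collapsed && (all_coil || !s_collapsed)) {
    note("coil branch: F not collapsed")
    if (s_extended) {
      note("ext_S=%.3g > %.3g: S blocks extended", f$ext_S, th$ext_cut)
      return(list(label = "Ib", trace = trace))
    }
    note("ext_S=%.3g <= %.3g", f$ext_S, th$ext_cut)
    return(list(label = "Ia", trace = trace))
  }
  note("globule branch: F collapsed or chain compact")
  s_pl <- if (!is.null(f$s_planar) && is.finite(f$s_planar)) f$s_planar else 0
  aniso <- f$s_nem > th$nematic_cut || s_pl > th$planar_cut
  note("s_nem=%.3g vs cut %.3g; s_planar=%.3g vs cut %.3g", f$s_nem,
       th$nematic_cut, s_pl, th$planar_cut)
  if (!aniso) {
    if (f_collapsed && !s_collapsed &&
        (s_extended || f$rg2_S >= th$coil_frac * ref_s)) {
      note("only F blocks collapsed (rg2_S=%.3g): flower/tadpole", f$rg2_S)
      return(list(label = "IIc", trace = trace))
    }
    note("contacts per bead %.3g vs frozen cut %.3g", contacts_per_bead,
         th$frozen_contacts)
    lbl <- if (contacts_per_bead >= th$frozen_contacts) "IIb" else "IIa"
    return(list(label = lbl, trace = trace))
  }
  # anisotropic globule sub-labels
  oblate_s <- f$prol_S < th$oblate_cut
  prolate_s <- f$prol_S > th$prolate_cut
  note("prol_S=%.3g (oblate<%.3g, prolate>%.3g)", f$prol_S, th$oblate_cut,
       th$prolate_cut)
  if (oblate_s) {
    hole <- TRUE
    if (!is.null(coords)) {
      s_idx <- which(model$types == 1L)
      sc <- coords[s_idx, , drop = FALSE]
      ctr <- colMeans(sc)
      hole <- min(sqrt(rowSums(sweep(sc, 2, ctr)^2))) > th$hole_radius
      note("hole test: min S-bead distance to S centroid %s %.3g",
           if (hole) ">" else "<=", th$hole_radius)
    } else note("hole test skipped (no coordinates): oblate S shell => toroid")
    if (hole) {
      note("oblate S subset with central hole: Saturn-like")
      return(list(label = "IIId", trace = trace))
    }
  }
  if (f$n_folds >= 1) {
    adsorbed <- f$nsf / n_f >= th$adsorb_contacts
    note("n_folds=%d >= 1: folded lamellar; nsf per F bead %.3g vs %.3g",
         as.integer(f$n_folds), f$nsf / n_f, th$adsorb_contacts)
    return(list(label = if (adsorbed) "IIIe" else "IIIe'", trace = trace))
  }
  if (prolate_s) {
    # dumbbell when the F beads cap the ends of the S bundle: F centroid
    # displaced along the long axis from the S centroid
    if (!is.null(coords)) {
      s_idx <- which(model$types == 1L); f_idx <- which(model$types == 0L)
      dc <- sqrt(sum((colMeans(coords[f_idx, , drop = FALSE]) -
                      colMeans(coords[s_idx, , drop = FALSE]))^2))
      dumbbell <- dc > 0.5 * sqrt(f$lam1_S)
      note("F-S centroid offset %.3g vs 0.5*sqrt(lam1_S)=%.3g", dc,
           0.5 * sqrt(f$lam1_S))
    } else {
      dumbbell <- f$nsf / n_f < th$adsorb_contacts
      note("no coordinates: dumbbell if F shell loose (nsf per F %.3g < %.3g)",
           f$nsf / n_f, th$adsorb_contacts)
    }
    if (dumbbell) {
      note("prolate S bundle with F caps: dumbbell")
      return(list(label = "IIIa", trace = trace))
    }
    note("prolate S bundle, dense F shell, no folds: lamellar")
    return(list(label = "IIIc", trace = trace))
  }
  note("anisotropic, neither clearly oblate-with-hole nor prolate: tennis racket")
  list(label = "IIIb", trace = trace)
}

#' Per-macrostate morphology feature means
#'
#' Reshapes a production-run observable table into per-macrostate feature
#' rows (adding the shape parameters derived from the mean gyration-tensor
#' eigenvalues) so state-diagram regions can be labeled through their most
#' probable macrostates.
#'
#' @param table an `sf_obs` from [production_run()].
#' @return data.frame: one row per macrostate with `Env_raw`, `nst`,
#'   `count` and the feature columns of [morphology_features()].
#' @export
mean_features_by_macrostate <- function(table) {
  t <- table$table
  shape_cols <- function(l1, l2, l3, suffix) {
    tr <- l1 + l2 + l3
    out <- data.frame(a = l1 - (l2 + l3) / 2,
                      p = ifelse(tr > 0, (3 * l1 - tr) * (3 * l2 - tr) *
                                   (3 * l3 - tr) / tr^3, 0))
    names(out) <- paste0(c("asph_", "prol_"), suffix)
    out
  }
  cbind(t[c("Env_raw", "nst", "count")],
        t[c("rg2_all", "rg2_S", "rg2_F",
            "lam1_all", "lam2_all", "lam3_all",
            "lam1_S", "lam2_S", "lam3_S",
            "lam1_F", "lam2_F", "lam3_F")],
        shape_cols(t$lam1_all, t$lam2_all, t$lam3_all, "all"),
        shape_cols(t$lam1_S, t$lam2_S, t$lam3_S, "S"),
        shape_cols(t$lam1_F, t$lam2_F, t$lam3_F, "F"),
        t[c("s_nem", "s_planar", "nss", "nff", "nsf", "ext_S", "n_folds",
            "demix")])
}

#' Classify the most probable macrostate at a state-diagram point
#'
#' Evaluates the canonical macrostate distribution at `(T, eps_st)`, picks
#' its mode, and classifies that macrostate's mean features.
#'
#' @param dos an `sf_dos`.
#' @param table an `sf_obs` production table for the same model.
#' @param model the `sf_model`.
#' @param temperature,eps_st the state-diagram point.
#' @param thresholds an [sf_thresholds()].
#' @return list with `label`, `trace`, `Env_raw`, `nst`, `prob`.
#' @export
classify_region <- function(dos, table, model, temperature, eps_st = 0,
                            thresholds = sf_thresholds()) {
  rho <- macrostate_probability(dos, temperature, eps_st)
  feats <- mean_features_by_macrostate(table)
  feats <- feats[feats$count > 0, , drop = FALSE]
  # mode restricted to macrostates with sampled features
  mm <- merge(rho, feats, by = c("Env_raw", "nst"))
  if (nrow(mm) == 0) stop("no sampled macrostates at this state point")
  mm <- mm[order(-mm$prob), ]
  top <- mm[1, ]
  cl <- classify_morphology(top, model, thresholds)
  list(label = cl$label, trace = cl$trace, Env_raw = top$Env_raw,
       nst = top$nst, prob = top$prob)
}

#' Temperature derivative of the mean squared gyration radius
#'
#' Canonical reweighting of a per-macrostate `Rg^2` observable along an
#' inverse-temperature grid, differentiated centrally with respect to
#' `x = |eps_ff| / T`.  Its maxima indicate collapse transitions even where
#' the corresponding specific-heat maximum is smeared out.
#'
#' @param dos an `sf_dos`.
#' @param table an `sf_obs` with the `rg2_*` observables.
#' @param eps_st stiffness energy.
#' @param x_grid grid of `|eps_ff| / T`.
#' @param subset `"all"`, `"S"` or `"F"`.
#' @param min_prominence passed to the peak detector.
#' @return data.frame with `x`, `rg2`, `drg2_dx`; maxima of the derivative
#'   magnitude (`-drg2_dx`, collapse direction) in `attr(, "maxima")`.
#' @export
rg2_derivative_curve <- function(dos, table, eps_st, x_grid,
                                 subset = c("all", "S", "F"),
                                 min_prominence = 0) {
  subset <- match.arg(subset)
  col <- paste0("rg2_", subset)
  abs_ff <- abs(dos$model_info$raw_scale * dos$model_info$eps_raw[2])
  # resolve the observable once so missing macrostates are reported once
  mm <- merge(dos$table[c("Env_raw", "nst")],
              table$table[c("Env_raw", "nst", col)],
              by = c("Env_raw", "nst"), all.x = TRUE, sort = FALSE)
  mm <- mm[match(paste(dos$table$Env_raw, dos$table$nst),
                 paste(mm$Env_raw, mm$nst)), ]
  a <- mm[[col]]
  if (!all(is.finite(a)))
    warning(sprintf("observable '%s' missing on %d macrostate(s); masked",
                    col, sum(!is.finite(a))))
  rg2 <- vapply(x_grid, function(x)
    suppressWarnings(canonical_average(dos, a, abs_ff / x, eps_st)), 1.0)
  n <- length(x_grid)
  d <- rep(NA_real_, n)
  d[2:(n - 1)] <- (rg2[3:n] - rg2[1:(n - 2)]) / (x_grid[3:n] - x_grid[1:(n - 2)])
  out <- data.frame(x = x_grid, rg2 = rg2, drg2_dx = d)
  ok <- is.finite(d)
  attr(out, "maxima") <- if (sum(ok) >= 3)
    find_peaks(x_grid[ok], -d[ok], min_prominence = min_prominence)
  else data.frame()
  out
}
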