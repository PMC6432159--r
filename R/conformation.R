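# Gyration-tensor shape and orientation descriptors of the cis/trans
# sub-chains, aggregated on the scaled-time axis.

#' Shape factor eta = <Re^2> / <Rg^2>
#'
#' Ratio of the mean squared end-to-end distance to the mean squared
#' gyration radius.  Reference values: 12 for a long rod (exactly
#' `12 (N-1)/(N+1)` for N collinear, equally spaced beads), 6 for an ideal
#' coil, and 2 for a compact globule whose ends sit at random positions
#' inside it.
#'
#' @param pos An n x 3 position matrix (a single configuration, rows in
#'   chain order), or a list of such matrices (an ensemble; the two means
#'   are then taken across configurations before the ratio).
#' @return The dimensionless shape factor.
#' @export
shape_factor <- function(pos) {
  if (is.matrix(pos)) pos <- list(pos)
  re2 <- vapply(pos, function(p) sum((p[nrow(p), ] - p[1, ])^2), 0)
  rg2 <- vapply(pos, .rg2, 0)
  m <- mean(rg2)
  if (m <= 0)
    stop("all beads coincident: gyration radius is zero, eta undefined")
  mean(re2) / m
}

.rg2 <- function(p) {
  cm <- colMeans(p)
  mean(rowSums(sweep(p, 2, cm)^2))
}

#' Gyration tensor and its sorted eigenvalues
#'
#' `G_ab = (1/Nc) sum_i (r_i - r_cm)_a (r_i - r_cm)_b` over the bead set;
#' eigenvalues are returned sorted `lambda_1 >= lambda_2 >= lambda_3 >= 0`
#' and satisfy `sum(lambda) == Rg^2`.
#'
#' @param pos An n x 3 position matrix (n >= 1).
#' @return List with `tensor` (3 x 3), `eigenvalues` (decreasing), and
#'   `eigenvectors` (columns, matching order).
#' @export
gyration_tensor <- function(pos) {
  stopifnot(is.matrix(pos), ncol(pos) == 3, nrow(pos) >= 1)
  cm <- colMeans(pos)
  d <- sweep(pos, 2, cm)
  G <- crossprod(d) / nrow(pos)
  e <- eigen(G, symmetric = TRUE)   # eigen() sorts decreasing
  list(tensor = G, eigenvalues = pmax(e$values, 0), eigenvectors = e$vectors)
}

#' Asphericity and prolateness from gyration-tensor eigenvalues
#'
#' With `lbar = (l1 + l2 + l3) / 3`:
#' `A = ((l1-lbar)^2 + (l2-lbar)^2 + (l3-lbar)^2) / (6 lbar^2)` in `[0, 1]`
#' and `P = (l1-lbar)(l2-lbar)(l3-lbar) / lbar^3` in `[-0.25, 2]`.
#' A sphere gives (0, 0), a rod (1, 2), a flat disk (0.25, -0.25).
#'
#' @param l1,l2,l3 Eigenvalues with `l1 >= l2 >= l3 >= 0`; alternatively
#'   `l1` may be a length-3 vector.
#' @return List with `A` and `P`.
#' @export
asphericity_prolateness <- function(l1, l2 = NULL, l3 = NULL) {
  if (is.null(l2)) { l3 <- l1[3]; l2 <- l1[2]; l1 <- l1[1] }
  if (l1 < l2 || l2 < l3 || l3 < 0)
    stop("eigenvalues must satisfy l1 >= l2 >= l3 >= 0")
  lbar <- (l1 + l2 + l3) / 3
  if (lbar == 0) stop("all eigenvalues zero: shape descriptors undefined")
  A <- ((l1 - lbar)^2 + (l2 - lbar)^2 + (l3 - lbar)^2) / (6 * lbar^2)
  P <- (l1 - lbar) * (l2 - lbar) * (l3 - lbar) / lbar^3
  list(A = A, P = P)
}

#' Principal-axis polar and azimuthal angles
#'
#' The principal axis is the eigenvector of the largest gyration-tensor
#' eigenvalue, sign-fixed so its z-component is positive.  The polar angle
#' `theta = atan2(sqrt(e_x^2 + e_y^2), e_z)` lies in `[0, 180]` degrees and
#' the azimuthal angle `phi = atan2(e_y, e_x)` in `(-180, 180]`.
#'
#' @param g A [gyration_tensor()] result, or an n x 3 position matrix.
#' @return List with `theta_deg`, `phi_deg`, and `degenerate` (TRUE when
#'   `lambda_1 == lambda_2` and the axis is not unique).
#' @export
principal_angles <- function(g) {
  if (is.matrix(g)) g <- gyration_tensor(g)
  e1 <- g$eigenvectors[, 1]
  degenerate <- isTRUE(all.equal(g$eigenvalues[1], g$eigenvalues[2]))
  if (e1[3] < 0) e1 <- -e1
  theta <- atan2(sqrt(e1[1]^2 + e1[2]^2), e1[3]) * 180 / pi
  phi <- atan2(e1[2], e1[1]) * 180 / pi
  if (phi <= -180) phi <- phi + 360
  list(theta_deg = theta, phi_deg = phi, degenerate = degenerate)
}

#' Shape descriptors of a sub-chain per scaled-time bin
#'
#' For every stored frame of every run, the monomers inside the requested
#' region (cis "I" or trans "III"; pore monomers belong to neither) form
#' the sub-chain.  Frames are placed on the scaled-time axis and the
#' descriptors averaged within bins: `eta` as the ratio of the binned mean
#' `Re^2` and `Rg^2`, the others as plain bin means.  Sub-chains with
#' fewer than 2 monomers are skipped (counted in `n_skipped`).
#'
#' @param trajectories List of `trajectory` objects.
#' @param taus Per-run translocation times (same length), used to scale
#'   each run's clock when `scaling = "per-run"`.
#' @param region `"I"` or `"III"`.
#' @param n_bins Number of scaled-time bins on `[0, 1]`.
#' @param scaling `"per-run"` (each run spans `[0, 1]` using its own
#'   `tau_k`) or `"ensemble"` (all clocks scaled by `mean(taus)`).
#' @return A data.frame with one row per bin: `t_tilde` (bin center),
#'   `eta`, `A`, `P`, `theta_deg`, `phi_deg`, `Re2`, `Rg2`, `n_samples`,
#'   `n_skipped`.  Bins with no usable frame carry `NA` descriptors.
#' @export
conformation_timeseries <- function(trajectories, taus, region = c("I", "III"),
                                    n_bins = 20,
                                    scaling = c("per-run", "ensemble")) {
  region <- match.arg(region)
  scaling <- match.arg(scaling)
  if (inherits(trajectories, "trajectory")) trajectories <- list(trajectories)
  stopifnot(length(trajectories) == length(taus))
  tau_ref <- mean(taus)
  acc <- vector("list", length(trajectories))
  for (r in seq_along(trajectories)) {
    tr <- trajectories[[r]]
    denom <- if (scaling == "per-run") taus[r] else tau_ref
    wh <- tr$cfg$wall_thickness / 2
    rows <- lapply(seq_along(tr$frames), function(fi) {
      p <- tr$frames[[fi]][seq_len(tr$n_mono), , drop = FALSE]
      sel <- if (region == "I") p[, 3] < -wh else p[, 3] > wh
      tt <- tr$times[fi] / denom
      if (sum(sel) < 2)
        return(data.frame(t_tilde = tt, Re2 = NA, Rg2 = NA, A = NA, P = NA,
                          theta_deg = NA, phi_deg = NA, ok = FALSE))
      sub <- p[sel, , drop = FALSE]
      g <- gyration_tensor(sub)
      ap <- asphericity_prolateness(g$eigenvalues)
      an <- principal_angles(g)
      data.frame(t_tilde = tt,
                 Re2 = sum((sub[nrow(sub), ] - sub[1, ])^2),
                 Rg2 = sum(g$eigenvalues),
                 A = ap$A, P = ap$P,
                 theta_deg = an$theta_deg, phi_deg = an$phi_deg, ok = TRUE)
    })
    acc[[r]] <- do.call(rbind, rows)
  }
  all <- do.call(rbind, acc)
  breaks <- seq(0, 1, length.out = n_bins + 1)
  bin <- cut(pmin(pmax(all$t_tilde, 0), 1), breaks, include.lowest = TRUE,
             labels = FALSE)
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  out <- lapply(seq_len(n_bins), function(b) {
    rows <- all[which(bin == b), , drop = FALSE]
    okr <- rows[rows$ok, , drop = FALSE]
    data.frame(
      t_tilde = centers[b],
      eta = if (nrow(okr)) mean(okr$Re2) / mean(okr$Rg2) else NA_real_,
      A = if (nrow(okr)) mean(okr$A) else NA_real_,
      P = if (nrow(okr)) mean(okr$P) else NA_real_,
      theta_deg = if (nrow(okr)) mean(okr$theta_deg) else NA_real_,
      phi_deg = if (nrow(okr)) mean(okr$phi_deg) else NA_real_,
      Re2 = if (nrow(okr)) mean(okr$Re2) else NA_real_,
      Rg2 = if (nrow(okr)) mean(okr$Rg2) else NA_real_,
      n_samples = nrow(okr), n_skipped = sum(!rows$ok))
  })
  out <- do.call(rbind, out)
  attr(out, "region") <- region
  attr(out, "scaling") <- scaling
  out
}

#' Write a per-bin descriptor table as CSV
#'
#' @param tab A [conformation_timeseries()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_conformation_csv <- function(tab, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# region=%s scaling=%s units: t_tilde dimensionless, Re2/Rg2 sigma^2, angles deg",
                     attr(tab, "region"), attr(tab, "scaling")), con)
  utils::write.csv(tab, con, row.names = FALSE)
  invisible(path)
}
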