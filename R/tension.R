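# Bond-tension propagation diagnostics: tension profiles on the scaled
# (time x bond) grid, direct/contour distances to the pore, the
# straightened-section boundary, and the tension front.

#' Mean bond-tension profile on the scaled time x bond grid
#'
#' For every stored frame the `N - 1` bond lengths are computed; frames
#' are binned on the scaled-time axis (per-run clocks) and the tension is
#' obtained from the binned mean bond length, `f_n = k (<l_n> - l0)`.
#' The scaled translocation coordinate `<s~>` is averaged per bin as the
#' progress overlay.
#'
#' @param trajectories List of `trajectory` objects.
#' @param taus Per-run translocation times.
#' @param n_bins Scaled-time bins on `[0, 1]`.
#' @return Object of class `tension_profile`: list with `f` (n_bins x
#'   (N-1) matrix, kBT/sigma), `mean_length`, `t_tilde` (bin centers),
#'   `n_tilde` (bond index / N), `s_tilde` (mean per bin), `n_frames`
#'   per bin, `k`, `l0`, `N`.
#' @export
bond_tension_profile <- function(trajectories, taus, n_bins = 20) {
  if (inherits(trajectories, "trajectory")) trajectories <- list(trajectories)
  stopifnot(length(trajectories) == length(taus))
  cfg <- trajectories[[1]]$cfg
  N <- trajectories[[1]]$n_mono
  sum_l <- matrix(0, n_bins, N - 1)
  cnt <- integer(n_bins)
  sum_s <- numeric(n_bins)
  breaks <- seq(0, 1, length.out = n_bins + 1)
  wh <- cfg$wall_thickness / 2
  for (r in seq_along(trajectories)) {
    tr <- trajectories[[r]]
    for (fi in seq_along(tr$frames)) {
      tt <- tr$times[fi] / taus[r]
      b <- min(max(findInterval(tt, breaks, rightmost.closed = TRUE), 1),
               n_bins)
      p <- tr$frames[[fi]][seq_len(N), , drop = FALSE]
      dl <- sqrt(rowSums((p[-1, , drop = FALSE] -
                            p[-N, , drop = FALSE])^2))
      sum_l[b, ] <- sum_l[b, ] + dl
      cnt[b] <- cnt[b] + 1L
      sum_s[b] <- sum_s[b] + sum(p[, 3] > wh) / N
    }
  }
  mean_l <- sum_l / ifelse(cnt > 0, cnt, NA)
  structure(list(
    f = cfg$k * (mean_l - cfg$l0),
    mean_length = mean_l,
    t_tilde = (breaks[-1] + breaks[-length(breaks)]) / 2,
    n_tilde = seq_len(N - 1) / N,
    s_tilde = ifelse(cnt > 0, sum_s / cnt, NA),
    n_frames = cnt, k = cfg$k, l0 = cfg$l0, N = N
  ), class = "tension_profile")
}

#' Direct and contour distances of every monomer to the pore
#'
#' `D_n` is the Euclidean distance from monomer n to the pore entrance on
#' its own side (the intersection of the pore axis with the wall face
#' nearer the monomer); `Lambda_n` is the contour distance: the sum of
#' bond lengths from n along the backbone to the last monomer outside the
#' pore region, plus that monomer's direct distance.  Both are exactly
#' zero for monomers inside region II.  With this convention
#' `Lambda_n >= D_n` by the triangle inequality.
#'
#' If no monomer is inside the pore region (pre-release or
#' post-completion), distances are computed toward the monomer nearest a
#' pore mouth and the result is flagged.
#'
#' @param pos N x 3 matrix of monomer positions in chain order (or a
#'   `particle_state`).
#' @param cfg A [system_config()] (taken from the state if given).
#' @return data.frame with `n`, `region`, `D`, `Lambda`, and attribute
#'   `flagged`.
#' @export
pore_distances <- function(pos, cfg = NULL) {
  if (inherits(pos, "particle_state")) {
    cfg <- pos$cfg
    pos <- pos$pos[seq_len(pos$n_mono), , drop = FALSE]
  }
  stopifnot(!is.null(cfg))
  N <- nrow(pos)
  wh <- cfg$wall_thickness / 2
  reg <- classify_regions(pos[, 3], cfg$wall_thickness)
  entrance <- function(i) c(0, 0, if (pos[i, 3] > 0) wh else -wh)
  d_entrance <- vapply(seq_len(N), function(i)
    sqrt(sum((pos[i, ] - entrance(i))^2)), 0)
  bond_len <- sqrt(rowSums((pos[-1, , drop = FALSE] -
                              pos[-N, , drop = FALSE])^2))
  in_pore <- which(reg == "II")
  flagged <- length(in_pore) == 0
  D <- numeric(N)
  Lam <- numeric(N)
  if (!flagged) {
    for (i in seq_len(N)) {
      if (reg[i] == "II") next
      D[i] <- d_entrance[i]
      j <- in_pore[which.min(abs(in_pore - i))]
      # walk from i toward j: last monomer before entering the pore
      b <- j - sign(j - i)   # last monomer before entering the pore
      contour <- if (i == b) 0 else
        sum(bond_len[seq(min(i, b), max(i, b) - 1)])
      Lam[i] <- contour + d_entrance[b]
    }
  } else {
    anchor <- which.min(d_entrance)
    for (i in seq_len(N)) {
      D[i] <- d_entrance[i]
      contour <- if (i == anchor) 0 else
        sum(bond_len[seq(min(i, anchor), max(i, anchor) - 1)])
      Lam[i] <- contour + d_entrance[anchor]
    }
  }
  out <- data.frame(n = seq_len(N), region = reg, D = D, Lambda = Lam)
  attr(out, "flagged") <- flagged
  out
}

#' Ensemble-averaged pore-distance profiles per scaled-time bin
#'
#' Averages `D_n` and `Lambda_n` over frames and runs within scaled-time
#' bins; single-run zeros inside the pore survive only where the pore
#' monomers coincide across runs.
#'
#' @inheritParams bond_tension_profile
#' @return List with `D`, `Lambda` (n_bins x N matrices), `t_tilde`,
#'   `n_tilde`.
#' @export
pore_distance_profile <- function(trajectories, taus, n_bins = 20) {
  if (inherits(trajectories, "trajectory")) trajectories <- list(trajectories)
  cfg <- trajectories[[1]]$cfg
  N <- trajectories[[1]]$n_mono
  sum_D <- matrix(0, n_bins, N)
  sum_L <- matrix(0, n_bins, N)
  cnt <- integer(n_bins)
  breaks <- seq(0, 1, length.out = n_bins + 1)
  for (r in seq_along(trajectories)) {
    tr <- trajectories[[r]]
    for (fi in seq_along(tr$frames)) {
      tt <- tr$times[fi] / taus[r]
      b <- min(max(findInterval(tt, breaks, rightmost.closed = TRUE), 1),
               n_bins)
      pd <- pore_distances(tr$frames[[fi]][seq_len(N), , drop = FALSE], cfg)
      sum_D[b, ] <- sum_D[b, ] + pd$D
      sum_L[b, ] <- sum_L[b, ] + pd$Lambda
      cnt[b] <- cnt[b] + 1L
    }
  }
  list(D = sum_D / ifelse(cnt > 0, cnt, NA),
       Lambda = sum_L / ifelse(cnt > 0, cnt, NA),
       t_tilde = (breaks[-1] + breaks[-length(breaks)]) / 2,
       n_tilde = seq_len(N) / N, n_frames = cnt)
}

#' Boundary of the straightened cis-side chain section
#'
#' Given the averaged profiles ordered from the pore outward along the cis
#' sub-chain, the straightened section is the largest contour depth such
#' that every monomer between the pore and that depth has
#' `<D> / <Lambda> >= threshold`; 0 if already the first monomer fails.
#'
#' @param D,Lambda Averaged distances ordered from the pore outward.
#' @param threshold Ratio threshold (default 0.9).
#' @return Integer boundary depth (number of straightened monomers).
#' @export
straightened_section <- function(D, Lambda, threshold = 0.9) {
  stopifnot(length(D) == length(Lambda))
  ratio <- ifelse(Lambda > 0, D / Lambda, 1)
  bad <- which(ratio < threshold)
  if (!length(bad)) length(ratio) else bad[1] - 1L
}

#' Locate the tension front on a single-time tension profile
#'
#' Scanning from the chain's free end (bond index N-1) toward the pore,
#' the front is the deepest cis bond whose mean tension exceeds the
#' trans-side background by the detection threshold.  When no bond
#' qualifies the front is absent (weak-field case).
#'
#' @param f Tension profile over bonds `1..N-1` (kBT/sigma).
#' @param background Trans-plateau background level; when `NULL` it is
#'   estimated as the mean tension of the trans-side bonds
#'   `n <= s_tilde * N`.
#' @param threshold Excess over background required; when `NULL`, 3
#'   standard deviations of the trans-plateau tensions (the plateau scatter
#'   sets the per-bond noise floor of the averaged profile, so a
#'   noise-band rule avoids false fronts on flat profiles).
#' @param s_tilde Scaled translocation coordinate of the profile's time
#'   bin (used for the background estimate).
#' @param N Chain length (default `length(f) + 1`).
#' @return List with `found`, `n_front` (bond index, `NA` when absent),
#'   `n_tilde`, `background`, `threshold`.
#' @export
tension_front <- function(f, background = NULL, threshold = NULL,
                          s_tilde = NULL, N = length(f) + 1) {
  ok <- is.finite(f)
  if (is.null(background) || is.null(threshold)) {
    if (is.null(s_tilde))
      stop("either a background level or s_tilde (for the trans-plateau ",
           "estimate) must be given")
    trans <- which(ok)[which(ok) <= max(1, floor(s_tilde * N))]
    if (length(trans) < 2)
      stop("too few trans-side bonds to estimate the background")
    if (is.null(background)) background <- mean(f[trans])
    if (is.null(threshold)) threshold <- 3 * stats::sd(f[trans])
  }
  above <- which(ok & f > background + threshold)
  if (!length(above))
    return(list(found = FALSE, n_front = NA_integer_, n_tilde = NA_real_,
                background = background, threshold = threshold))
  n_front <- max(above)   # deepest cis bond, scanning free end -> pore
  list(found = TRUE, n_front = n_front, n_tilde = n_front / N,
       background = background, threshold = threshold)
}

#' Export a tension intensity map as dense CSV
#'
#' One row per scaled-time bin, one column per scaled bond index, plus a
#' sidecar column for the `<s~>` overlay, sufficient to re-plot the
#' intensity map.
#'
#' @param profile A [bond_tension_profile()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tension_csv <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# bond tension map, kBT/sigma; N=%d k=%g l0=%g",
                     profile$N, profile$k, profile$l0), con)
  df <- data.frame(t_tilde = profile$t_tilde, s_tilde = profile$s_tilde,
                   profile$f)
  names(df)[-(1:2)] <- sprintf("f_n%03d", seq_len(ncol(profile$f)))
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}
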