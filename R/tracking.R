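# Region classification, translocation coordinate, waiting-time statistics.

#' Classify z-coordinates into cis / pore / trans regions
#'
#' With the wall centered at z = 0: `z < -w/2` is the cis region (I),
#' `|z| <= w/2` the pore region (II, closed interval), `z > w/2` the trans
#' region (III).
#'
#' @param z Numeric z-coordinates (sigma).
#' @param wall_thickness Wall thickness w (sigma).
#' @return Character vector of `"I"`, `"II"`, `"III"`.
#' @export
classify_regions <- function(z, wall_thickness = 4.5) {
  wh <- wall_thickness / 2
  ifelse(z < -wh, "I", ifelse(z > wh, "III", "II"))
}

#' Translocation coordinate s
#'
#' The number of chain monomers in the trans region (III).
#'
#' @param x A `particle_state`, or a matrix of monomer positions.
#' @param wall_thickness Wall thickness (sigma); taken from the state's
#'   config when available.
#' @return Integer s in `0..N`.
#' @export
translocation_coordinate <- function(x, wall_thickness = 4.5) {
  if (inherits(x, "particle_state")) {
    z <- x$pos[seq_len(x$n_mono), 3]
    wall_thickness <- x$cfg$wall_thickness
  } else {
    z <- x[, 3]
  }
  sum(z > wall_thickness / 2)
}

#' Waiting time per translocation state
#'
#' The waiting time `w_k(s)` is the total time a run dwells at coordinate
#' `s`, accumulated over revisits, for `s = 1..N-1`; the terminal state `N`
#' is excluded (the chain dwells there permanently once threading is
#' complete).  By construction `sum(w_k) == tau_k` exactly, where `tau_k`
#' is the time of first arrival at `s = N`.
#'
#' @param s Integer series of the translocation coordinate.
#' @param time Time stamps of the same length (tau_u).
#' @param N Chain length; defaults to `max(s)`.
#' @return Numeric vector `w` of length `N - 1`, names `1..N-1`, with
#'   attribute `tau`.
#' @export
waiting_times <- function(s, time = seq_along(s) - 1, N = max(s)) {
  stopifnot(length(s) == length(time))
  idx <- which(s >= N)
  if (!length(idx))
    stop("series never reaches s = N: incomplete run has no waiting times")
  end <- idx[1]
  w <- numeric(N - 1)
  if (end > 1) {
    occ <- s[seq_len(end - 1)]
    dtv <- diff(time[seq_len(end)])
    keep <- occ >= 1 & occ <= N - 1
    tw <- tapply(dtv[keep], occ[keep], sum)
    w[as.integer(names(tw))] <- as.numeric(tw)
  }
  names(w) <- seq_len(N - 1)
  attr(w, "tau") <- time[end] - time[1]
  w
}

#' Aggregate waiting times over an ensemble of runs
#'
#' Computes the mean waiting time `w(s)` over the `M` completed runs, the
#' mean translocation time, and the normalized waiting-time function
#' `w~(s~) = N w(s) / <tau>` on the scaled coordinate `s~ = s/N`, which
#' integrates to one over `[0, 1]`.
#'
#' @param records List of `translocation_record` objects (or numeric
#'   waiting-time vectors).
#' @param N Chain length; taken from the first record when available.
#' @return An object of class `ensemble_record`: list with `M`, `tau_mean`,
#'   `w` (mean waiting time per state), `w_tilde` (data.frame `s_tilde`,
#'   `w_tilde`), and `records`.
#' @export
ensemble_waiting <- function(records, N = NULL) {
  if (inherits(records, "translocation_record")) records <- list(records)
  ws <- lapply(records, function(r) {
    if (inherits(r, "translocation_record")) {
      if (!isTRUE(r$completed)) return(NULL)
      r$w
    } else r
  })
  ws <- ws[!vapply(ws, is.null, TRUE)]
  if (!length(ws)) stop("no completed runs: empty ensemble")
  if (is.null(N)) {
    N <- if (inherits(records[[1]], "translocation_record"))
      records[[1]]$N else length(ws[[1]]) + 1L
  }
  stopifnot(all(vapply(ws, length, 0L) == N - 1))
  taus <- vapply(ws, function(w) attr(w, "tau"), 0)
  wbar <- Reduce(`+`, lapply(ws, as.numeric)) / length(ws)
  tau_mean <- mean(taus)
  s_tilde <- seq_len(N - 1) / N
  structure(list(M = length(ws), tau_mean = tau_mean, tau = taus, w = wbar,
                 w_tilde = data.frame(s_tilde = s_tilde,
                                      w_tilde = N * wbar / tau_mean),
                 N = N, records = records),
            class = "ensemble_record")
}

#' @export
print.ensemble_record <- function(x, ...) {
  cat(sprintf("Ensemble: M = %d completed runs, N = %d, <tau> = %.4g tau_u\n",
              x$M, x$N, x$tau_mean))
  invisible(x)
}

#' Integral of the normalized waiting-time function
#'
#' Riemann sum of `w~(s~)` over `s~ in [0, 1]` at the state resolution
#' `1/N`; exactly one by the normalization identity
#' `sum_s w(s) * N / <tau> * (1/N) = sum_s w(s) / <tau> = 1`.
#'
#' @param ens An [ensemble_waiting()] result.
#' @return The integral (numeric scalar).
#' @export
w_tilde_integral <- function(ens) {
  sum(ens$w_tilde$w_tilde) / ens$N
}

#' Export waiting-time tables as CSV
#'
#' @param ens An `ensemble_record`.
#' @param path Output CSV path.
#' @param cfg Optional [system_config()] for the header comment.
#' @return `path`, invisibly.
#' @export
write_waiting_csv <- function(ens, path, cfg = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  seeds <- vapply(ens$records, function(r)
    if (inherits(r, "translocation_record")) r$seed else NA_integer_, 0)
  hdr <- sprintf("# N=%d M=%d tau_mean_tau_u=%.10g seeds=%s%s",
                 ens$N, ens$M, ens$tau_mean,
                 paste(seeds, collapse = "|"),
                 if (!is.null(cfg)) sprintf(" E=%g", cfg$E) else "")
  writeLines(c(hdr, "s,s_tilde,w_tau_u,w_tilde"), con)
  utils::write.table(
    data.frame(seq_len(ens$N - 1), ens$w_tilde$s_tilde, ens$w,
               ens$w_tilde$w_tilde),
    con, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}
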