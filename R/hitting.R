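# Replay detectors for hitting times: pure functions of a stored event log.
# The same detections run online inside simulate_population(); replay exists
# so logs can be re-analysed (and so determinism can be verified).

#' A hitting record
#'
#' @param event one of `"tau_rep"`, `"tau_R"`, `"tau_min"`, `"tau_v"`.
#' @param time hitting time, or `NA` when censored.
#' @param censor_time end time of the trajectory when censored.
#' @param theta optional named parameter vector.
#' @param replicate,seed optional bookkeeping fields.
#' @return list of class `hitting_record` with exactly one of
#'   `time`/`censored` informative.
#' @export
hitting_record <- function(event, time = NA_real_, censor_time = NA_real_,
                           theta = NULL, replicate = NA_integer_,
                           seed = NA_integer_) {
  censored <- is.na(time)
  if (censored && is.na(censor_time))
    stop("a censored record must carry its censor time")
  structure(list(event = event, time = time, censored = censored,
                 censor_time = if (censored) censor_time else NA_real_,
                 theta = theta, replicate = replicate, seed = seed),
            class = "hitting_record")
}

#' @export
print.hitting_record <- function(x, ...) {
  cat(x$event, ":", if (x$censored) paste0("censored at ", signif(x$censor_time, 5))
      else signif(x$time, 5), "\n")
  invisible(x)
}

#' Replay the volume-fraction process from an event log
#'
#' Reconstructs `K_t` and `V_t` (and the count of high-fidelity molecules)
#' from the initial population and the logged events, independently of the
#' series the simulator recorded.
#'
#' @param traj an `rna_trajectory`.
#' @param R high-fidelity set; defaults to the one stored on the trajectory.
#' @return data frame with columns `time`, `K`, `nXR`, `V`, one row per
#'   event plus the initial state at time 0.
#' @export
replay_volume_fraction <- function(traj, R = NULL) {
  n <- traj$n
  codes <- if (is.null(R)) traj$R else manifold_codes(R, n)
  mE <- 4^n
  comp <- complement_code(0:(mE - 1L), n)
  in_R <- logical(mE); in_R[codes + 1L] <- TRUE
  dupR <- in_R | in_R[comp + 1L]
  Ns <- traj$init$Ns; Nd <- traj$init$Nd
  K <- traj$init$K
  nXR <- sum(Ns[in_R]) + sum(Nd[dupR])
  ev <- traj$events
  m <- nrow(ev)
  out_K <- integer(m + 1L); out_n <- integer(m + 1L)
  out_K[1L] <- K; out_n[1L] <- nXR
  if (m > 0) for (i in seq_len(m)) {
    switch(ev$channel[i],
      ds_form = {
        nXR <- nXR - in_R[ev$r1[i] + 1L] - in_R[ev$r2[i] + 1L] +
          dupR[ev$prod[i] + 1L]
        K <- K - 1L
      },
      ds_dissoc = {
        xc <- comp[ev$prod[i] + 1L]
        nXR <- nXR - dupR[ev$r1[i] + 1L] + in_R[ev$prod[i] + 1L] + in_R[xc + 1L]
        K <- K + 1L
      },
      decay = {
        nXR <- nXR - in_R[ev$r1[i] + 1L]
        K <- K - 1L
      },
      {
        nXR <- nXR + in_R[ev$prod[i] + 1L]
        K <- K + 1L
      })
    out_K[i + 1L] <- K; out_n[i + 1L] <- nXR
  }
  data.frame(time = c(0, ev$time), K = out_K, nXR = out_n,
             V = ifelse(out_K > 0, out_n / out_K, NA_real_))
}

#' Hitting-time detectors on a trajectory
#'
#' `detect_tau_rep`: first time the molecule count exceeds the initial size.
#' `detect_tau_R`: first time a high-fidelity sequence is present (free or
#' inside a duplex). `detect_tau_min`: time the running minimum of the
#' volume fraction on `[tau_R, end]` is attained (last attainment by
#' default). `detect_tau_v`: first time `V(t) >= v`. All return censored
#' records (censor time = trajectory end time) when the condition never
#' fires within the log.
#'
#' @param traj an `rna_trajectory`.
#' @param R high-fidelity set; defaults to the trajectory's.
#' @param v volume-fraction threshold in `(0, 1]` (`v = 0` hits at time 0).
#' @param first if `TRUE`, tau_min is the first attainment of the minimum.
#' @return a `hitting_record`.
#' @export
detect_tau_rep <- function(traj) {
  grow <- which(c(traj$init$K, traj$events$K)[-1L] > traj$I)
  if (length(grow) == 0L)
    return(hitting_record("tau_rep", censor_time = traj$end_time))
  hitting_record("tau_rep", time = traj$events$time[grow[1L]])
}

#' @rdname detect_tau_rep
#' @export
detect_tau_R <- function(traj, R = NULL) {
  vf <- replay_volume_fraction(traj, R)
  idx <- which(vf$nXR >= 1L)
  if (length(idx) == 0L)
    return(hitting_record("tau_R", censor_time = traj$end_time))
  hitting_record("tau_R", time = vf$time[idx[1L]])
}

#' @rdname detect_tau_rep
#' @export
detect_tau_min <- function(traj, R = NULL, first = FALSE) {
  vf <- replay_volume_fraction(traj, R)
  idx <- which(vf$nXR >= 1L)
  if (length(idx) == 0L)
    return(hitting_record("tau_min", censor_time = traj$end_time))
  sub <- vf[idx[1L]:nrow(vf), ]
  vmin <- min(sub$V, na.rm = TRUE)
  at <- which(sub$V == vmin)
  hitting_record("tau_min",
                 time = sub$time[if (first) at[1L] else at[length(at)]])
}

#' @rdname detect_tau_rep
#' @export
detect_tau_v <- function(traj, v, R = NULL) {
  if (v < 0 || v > 1) stop("v must lie in [0, 1]")
  vf <- replay_volume_fraction(traj, R)
  idx <- which(!is.na(vf$V) & vf$V >= v)
  if (length(idx) == 0L)
    return(hitting_record("tau_v", censor_time = traj$end_time))
  hitting_record("tau_v", time = vf$time[idx[1L]])
}

#' All hitting records of a trajectory, by replay
#'
#' @inheritParams detect_tau_rep
#' @param v volume-fraction threshold; defaults to the trajectory's.
#' @param first passed to [detect_tau_min()].
#' @return named list of `hitting_record`s
#'   (`tau_rep`, `tau_R`, `tau_min`, `tau_v`).
#' @export
hitting_records <- function(traj, R = NULL, v = traj$v, first = FALSE) {
  out <- list(tau_rep = detect_tau_rep(traj),
              tau_R = detect_tau_R(traj, R),
              tau_min = detect_tau_min(traj, R, first = first))
  if (!is.null(v)) out$tau_v <- detect_tau_v(traj, v, R)
  out
}
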