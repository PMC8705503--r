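# Configuration, serialization and run outputs: YAML run configs, FASTA for
# sequence sets and populations, JSONL event logs, CSV measure series, and a
# reproducibility manifest.

#' Read and write sequence sets as FASTA
#'
#' Populations are written one record per species with a `count=` annotation
#' in the description; `read_fasta_population` reconstructs the counts.
#'
#' @param path file path.
#' @return `read_fasta_sequences`: character vector of sequences.
#'   `read_fasta_population`: an `rna_population`.
#' @export
read_fasta_sequences <- function(path) {
  set <- Biostrings::readBStringSet(path)
  toupper(gsub("T", "U", as.character(set)))
}

#' @rdname read_fasta_sequences
#' @param pop an `rna_population`.
#' @export
write_fasta_population <- function(pop, path) {
  stopifnot(inherits(pop, "rna_population"))
  s_idx <- which(pop$Ns > 0L)
  d_idx <- which(pop$Nd > 0L)
  seqs <- c(rna_decode(s_idx - 1L, pop$n), rna_decode(d_idx - 1L, pop$n))
  names(seqs) <- c(
    sprintf("single_%s count=%d", rna_decode(s_idx - 1L, pop$n), pop$Ns[s_idx]),
    sprintf("duplex_%s count=%d", rna_decode(d_idx - 1L, pop$n), pop$Nd[d_idx]))
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' @rdname read_fasta_sequences
#' @export
read_fasta_population <- function(path) {
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(gsub("T", "U", as.character(set)))
  hdr <- names(set)
  counts <- as.integer(sub(".*count=(\\d+).*", "\\1", hdr))
  counts[is.na(counts)] <- 1L
  dup <- grepl("^duplex", hdr)
  population(singles = rep(seqs[!dup], counts[!dup]),
             duplexes = if (any(dup)) rep(seqs[dup], counts[dup]) else NULL,
             n = nchar(seqs[[1L]]))
}

config_defaults <- function() {
  list(
    space = list(n = 3L, cap = 8L),
    landscape = list(form = "tent", terminus_f = 0.01, terminus_s = 0.01,
                     terminus_p = 0.25, similarity = "distance", b = 1),
    manifold = list(q = 0, members = NULL, fasta = NULL),
    rates = list(kds = 1, kss = 1, krep_scale = 10, calibrate_mass = NULL,
                 kdecay = 0, kclay_o = 0, kclay_p = 0, p_clay = 0.9,
                 kmic = 0),
    init = list(I = 10L, avoid_R = FALSE),
    stop = list(budget = 5000L, v = 0.25, stop_at = "tau_v"),
    output = list(record_mu = FALSE, mu_every = 10L),
    seed = 1L
  )
}

#' Load and validate a run configuration
#'
#' YAML with sections `space`, `landscape`, `manifold`, `rates`, `init`,
#' `stop`, `output`, `seed`; missing fields take the model's defaults
#' (kss = kds = 1, replication scale 10, fidelity terminus 0.25, budget
#' 5000). Unknown sections or fields are rejected.
#'
#' @param path YAML file path.
#' @return validated config list of class `run_config`.
#' @export
load_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  # YAML 1.1 reads the bare key `n` as the boolean FALSE; restore it
  if (!is.null(raw$space) && "FALSE" %in% names(raw$space))
    names(raw$space)[names(raw$space) == "FALSE"] <- "n"
  defaults <- config_defaults()
  bad <- setdiff(names(raw), names(defaults))
  if (length(bad)) stop("unknown config section(s): ", paste(bad, collapse = ", "))
  cfg <- defaults
  for (sec in names(raw)) {
    if (!is.list(defaults[[sec]])) { cfg[[sec]] <- raw[[sec]]; next }
    extra <- setdiff(names(raw[[sec]]), names(defaults[[sec]]))
    if (length(extra))
      stop("unknown field(s) in [", sec, "]: ", paste(extra, collapse = ", "))
    cfg[[sec]] <- utils::modifyList(defaults[[sec]], raw[[sec]])
  }
  with(cfg, {
    if (space$n < 1) stop("space.n must be >= 1")
    if (!landscape$form %in% c("tent", "linear")) stop("landscape.form must be tent or linear")
    for (f in c("terminus_f", "terminus_s", "terminus_p"))
      if (landscape[[f]] <= 0 || landscape[[f]] > 1)
        stop("landscape.", f, " must lie in (0, 1]")
    if (init$avoid_R && is.null(manifold$q) && is.null(manifold$members) &&
        is.null(manifold$fasta))
      stop("init.avoid_R requires a manifold specification")
    if (stop$budget < 0) stop("stop.budget must be >= 0")
  })
  structure(cfg, class = "run_config")
}

#' Run a simulation from a configuration
#'
#' @param cfg a `run_config` (or path to one).
#' @param seed overrides the config seed when non-`NULL`.
#' @return an `rna_trajectory` with the config attached.
#' @export
run_from_config <- function(cfg, seed = NULL) {
  if (is.character(cfg)) cfg <- load_run_config(cfg)
  if (is.null(seed)) seed <- cfg$seed
  set.seed(seed)
  n <- cfg$space$n
  man <- cfg$manifold
  R <- if (!is.null(man$members)) build_manifold(n = n, members = man$members)
    else if (!is.null(man$fasta)) build_manifold(members = read_fasta_sequences(man$fasta))
    else build_manifold(n = n, q = man$q)
  lsc <- cfg$landscape
  ls <- landscape(R, form = lsc$form,
                  k = curvature_from_terminus(lsc$terminus_f, n),
                  l = curvature_from_terminus(lsc$terminus_s, n),
                  m = curvature_from_terminus(lsc$terminus_p, n),
                  terminus_f = lsc$terminus_f, terminus_s = lsc$terminus_s,
                  terminus_p = lsc$terminus_p,
                  a = cfg$rates$krep_scale,
                  similarity = lsc$similarity, b = lsc$b)
  pop <- init_population(n, cfg$init$I, R, avoid_R = cfg$init$avoid_R)
  if (!is.null(cfg$rates$calibrate_mass))
    ls$a <- calibrate_replication_scale(pop, ls, cfg$rates$calibrate_mass)
  rates <- reaction_rates(kds = cfg$rates$kds, kss = cfg$rates$kss,
                          kdecay = cfg$rates$kdecay,
                          kclay_o = cfg$rates$kclay_o,
                          kclay_p = cfg$rates$kclay_p,
                          p_clay = cfg$rates$p_clay, kmic = cfg$rates$kmic)
  tr <- simulate_population(ls, pop, rates, budget = cfg$stop$budget,
                            v = cfg$stop$v, stop_at = cfg$stop$stop_at,
                            record_mu = cfg$output$record_mu,
                            mu_every = cfg$output$mu_every)
  tr$config <- cfg
  tr$seed <- seed
  tr
}

#' Write the artifacts of a run
#'
#' Writes the event log (`events.jsonl`), the measure time series
#' (`measures.csv`: time, reaction index, class, count, concentration and
#' image-measure mass when recorded), the final population
#' (`population.fasta`) and a reproducibility manifest (`manifest.json`:
#' config, seed, hitting records).
#'
#' @param traj an `rna_trajectory`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_run_outputs <- function(traj, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  con <- file(file.path(dir, "events.jsonl"), "w")
  jsonlite::stream_out(traj$events, con, verbose = FALSE)
  close(con)

  n <- traj$n
  idx <- 0:traj$n_events
  times <- c(0, traj$events$time)
  Ks <- c(traj$init$K, traj$events$K)
  long <- do.call(rbind, lapply(0:n, function(cl) {
    cnt <- traj$class_counts[, cl + 1L]
    mu <- rep(NA_real_, length(idx))
    if (!is.null(traj$mu)) {
      pos <- match(round(traj$mu_times, 12), round(times, 12))
      mu[pos[!is.na(pos)]] <- traj$mu[!is.na(pos), cl + 1L]
    }
    data.frame(time = times, reaction_index = idx, class = cl,
               count = cnt, concentration = ifelse(Ks > 0, cnt / Ks, NA),
               mu_mass = mu)
  }))
  utils::write.csv(long, file.path(dir, "measures.csv"), row.names = FALSE)
  write_fasta_population(traj$final, file.path(dir, "population.fasta"))
  manifest <- list(seed = traj$seed, config = unclass(traj$config),
                   n = traj$n, I = traj$I, budget = traj$budget,
                   n_events = traj$n_events, stopped = traj$stopped,
                   hits = traj$hits)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(dir)
}

#' Write a sweep dataset as CSV
#'
#' @param sweep a `sweep_dataset`.
#' @param path output CSV path.
#' @export
write_sweep_csv <- function(sweep, path) {
  utils::write.csv(as.data.frame(sweep), path, row.names = FALSE)
  invisible(path)
}

#' Read a sweep dataset from CSV
#'
#' @param path CSV path written by [write_sweep_csv()].
#' @return a `sweep_dataset`.
#' @export
read_sweep_csv <- function(path) {
  out <- utils::read.csv(path)
  for (col in intersect(c("tau", "censor_time"), names(out)))
    out[[col]] <- as.numeric(out[[col]])   # all-NA columns read as logical
  class(out) <- c("sweep_dataset", "data.frame")
  out
}
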