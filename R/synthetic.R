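# Simulator-backed synthetic sequence sets: the Wright-Fisher engine doubles
# as the data generator for validating the inference pipeline end to end
# through the standard FASTA path.

#' Generate a synthetic time-stamped sequence set
#'
#' Runs an ensemble of replicate Wright-Fisher populations on a shared
#' selection landscape, samples `n_sample` genomes per replicate at each
#' requested time, and writes them as per-(replicate, time) FASTA files plus
#' a TSV sample sheet, i.e. exactly the input the inference pipeline
#' ([read_alignment_set()] then [run_inference()]) consumes. Sampling
#' genomes rather than exporting whole populations emulates sequencing a
#' finite sample from each population.
#'
#' @param params a [sim_params()] object (`n_replicates` populations).
#' @param profile a `selection_profile` shared by all replicates.
#' @param times generations at which to sample sequences.
#' @param n_sample genomes sampled per replicate per time (without
#'   replacement; default 200, capped at `N`).
#' @param dir output directory (created if needed).
#' @param mapping allele-to-residue mapping, as in
#'   [export_population_fasta()].
#' @return list with `sheet` (sample sheet path), `profile_file` (TSV of the
#'   true landscape), `trajectories` (the ensemble, for ground-truth
#'   comparison).
#' @export
simulate_alignment_set <- function(params, profile, times, n_sample = 200,
                                   dir = tempfile("seqset"),
                                   mapping = c("A", "G")) {
  times <- as.integer(sort(times))
  n_sample <- min(n_sample, params$N)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  record_times <- sort(unique(c(0L, times)))
  trajectories <- run_ensemble(params, profile, record_times = record_times,
                               checkpoint_times = times)
  rows <- list()
  for (r in seq_along(trajectories)) {
    for (t in times) {
      pop <- trajectories[[r]]$checkpoints[[as.character(t)]]
      fname <- sprintf("rep%02d_t%03d.fasta", r, t)
      export_population_fasta(pop, file.path(dir, fname), mapping = mapping,
                              time = t, replicate = r, sample_n = n_sample)
      rows[[length(rows) + 1L]] <- data.frame(file = fname, time = t,
                                              replicate = r)
    }
  }
  sheet <- file.path(dir, "samples.tsv")
  utils::write.table(do.call(rbind, rows), sheet, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  profile_file <- file.path(dir, "profile.tsv")
  write_selection_profile(profile, profile_file)
  list(sheet = sheet, profile_file = profile_file, trajectories = trajectories)
}
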