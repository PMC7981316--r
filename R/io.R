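#' Write a cohort to delimited text files
#'
#' Emits `patients.csv` and `assessments.csv` (the analysis-facing tables)
#' and, separately, `truth.csv` with the planted ground truth — the truth
#' table is never part of the analysis-facing files. The generator
#' configuration is written as `config.yml` (flat key/value text).
#'
#' @param cohort a `cohort`.
#' @param dir output directory (created if needed).
#' @param truth write the ground-truth table too? (default TRUE)
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir, truth = TRUE) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(patients = file.path(dir, "patients.csv"),
             assessments = file.path(dir, "assessments.csv"))
  write.csv(cohort$patients, paths["patients"], row.names = FALSE)
  write.csv(cohort$assessments, paths["assessments"], row.names = FALSE)
  if (truth && !is.null(cohort$truth)) {
    paths["truth"] <- file.path(dir, "truth.csv")
    write.csv(cohort$truth, paths["truth"], row.names = FALSE)
  }
  if (!is.null(cohort$config)) {
    paths["config"] <- file.path(dir, "config.yml")
    cfg <- cohort$config
    flat <- vapply(names(cfg), function(nm) {
      v <- cfg[[nm]]
      if (is.list(v)) v <- unlist(v)
      if (is.null(v)) "~" else paste(
        if (!is.null(names(v)) && any(nzchar(names(v))))
          paste0(names(v), "=", v) else as.character(v),
        collapse = ", ")
    }, character(1))
    writeLines(paste0(names(cfg), ": ", flat), paths["config"])
  }
  invisible(paths)
}

.required_patient_cols <- function() {
  c("patient_id", "diagnosis", "gender", "age", "ward", "drug_count",
    "igm", discovery_features(), "dl", "sl", "baseline_hamd17",
    "baseline_panss_p")
}

#' Read a cohort from delimited text files
#'
#' Reads `patients.csv` and `assessments.csv` (and `truth.csv` when
#' present) back into a `cohort`, validating the schema: mandatory
#' columns, unique patient identifiers, assessment keys referring to
#' existing patients, assessment days restricted to the study schedule,
#' and a day-0 record for every patient with assessments.
#'
#' @param dir directory containing the files (as written by
#'   [write_cohort()]).
#' @return a `cohort` (with `config = NULL`).
#' @export
read_cohort <- function(dir) {
  pfile <- file.path(dir, "patients.csv")
  afile <- file.path(dir, "assessments.csv")
  for (f in c(pfile, afile)) if (!file.exists(f)) stop("missing file: ", f)
  patients <- read.csv(pfile, stringsAsFactors = FALSE)
  assessments <- read.csv(afile, stringsAsFactors = FALSE)

  miss <- setdiff(.required_patient_cols(), names(patients))
  if (length(miss)) {
    stop("patients.csv lacks mandatory column(s): ",
         paste(miss, collapse = ", "))
  }
  dup <- patients$patient_id[duplicated(patients$patient_id)]
  if (length(dup)) {
    stop("duplicate patient id(s): ", paste(unique(dup), collapse = ", "))
  }
  if (!all(patients$diagnosis %in% c("F2", "F3"))) {
    stop("diagnosis must be F2 or F3")
  }
  orphan <- setdiff(assessments$patient_id, patients$patient_id)
  if (length(orphan)) {
    stop("assessments refer to unknown patient id(s): ",
         paste(head(orphan, 5), collapse = ", "))
  }
  bad_day <- setdiff(unique(assessments$day), study_schedule())
  if (length(bad_day)) {
    stop("assessment day(s) outside the study schedule {",
         paste(study_schedule(), collapse = ", "), "}: ",
         paste(bad_day, collapse = ", "))
  }
  has_day0 <- tapply(assessments$day == 0, assessments$patient_id, any)
  if (!all(has_day0)) {
    stop("patient(s) without a day-0 assessment: ",
         paste(head(names(has_day0)[!has_day0], 5), collapse = ", "))
  }
  tfile <- file.path(dir, "truth.csv")
  truth <- if (file.exists(tfile)) read.csv(tfile,
                                            stringsAsFactors = FALSE)
  else NULL
  structure(list(patients = patients, assessments = assessments,
                 truth = truth, config = NULL), class = "cohort")
}

# Tiny deterministic content hash (31-polynomial over the serialized
# text, mod 2^31) used to stamp outputs with their configuration.
.config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full analysis pipeline
#'
#' Generates (or loads) a cohort, then runs every enabled stage —
#' instrument scoring summary, pairwise concordance, subgroup discovery
#' per diagnosis, side-effect and polypharmacy variance analyses — and
#' writes all reports under `out_dir`. A `manifest.json` records the seed
#' and a configuration hash; a rerun with the same configuration is
#' byte-identical.
#'
#' @param config a `generator_config`, or a directory path holding cohort
#'   CSV files (exactly one input source).
#' @param out_dir output directory.
#' @param stages character subset of
#'   `c("summary", "concordance", "discovery", "variance")`.
#' @param discovery_diagnoses diagnosis classes to run discovery on.
#' @param seed seed for the analysis stages (generation uses the config's
#'   own seed).
#' @return invisibly, a list of the stage results.
#' @export
run_pipeline <- function(config = generator_config(), out_dir,
                         stages = c("summary", "concordance", "discovery",
                                    "variance"),
                         discovery_diagnoses = c("F2", "F3"),
                         seed = 1) {
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.character(config)) {
    cohort <- read_cohort(config)
    src <- paste0("dir:", config)
  } else {
    cohort <- generate_cohort(config)
    write_cohort(cohort, file.path(out_dir, "cohort"))
    src <- "generated"
  }
  res <- list()
  present <- intersect(c("F2", "F3"), unique(cohort$patients$diagnosis))
  discovery_diagnoses <- intersect(discovery_diagnoses, present)

  if ("summary" %in% stages) {
    res$summary <- cohort_summary(cohort)
    write.csv(res$summary, file.path(out_dir, "summary.csv"),
              row.names = FALSE)
  }
  if ("concordance" %in% stages) {
    cm <- pairwise_concordance(cohort)
    res$concordance <- cm
    write.csv(cm$pairs, file.path(out_dir, "concordance_pairs.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      list(mean = cm$mean, sd = cm$sd, n_pairs = cm$n_pairs, n = cm$n),
      file.path(out_dir, "concordance_summary.json"),
      auto_unbox = TRUE, digits = NA)
  }
  if ("discovery" %in% stages) {
    res$discovery <- list()
    for (di in discovery_diagnoses) {
      smp <- exclude_incomplete(cohort, di)
      mod <- subgroup_search(smp, seed = seed)
      ev <- subgroup_evaluate(mod, smp)
      res$discovery[[di]] <- list(sample = smp, model = mod, report = ev)
      jsonlite::write_json(
        c(ev[setdiff(names(ev), "scatter")],
          list(excluded = smp$report$text)),
        file.path(out_dir, sprintf("discovery_%s.json", di)),
        auto_unbox = TRUE, digits = NA)
      write.csv(ev$scatter,
                file.path(out_dir, sprintf("discovery_%s_scatter.csv", di)),
                row.names = FALSE)
    }
  }
  if ("variance" %in% stages) {
    se <- drug_side_effect_analysis(cohort)
    write.csv(se, file.path(out_dir, "variance_side_effects.csv"),
              row.names = FALSE)
    pd <- polypharmacy_determinants(cohort, seed = seed)
    jsonlite::write_json(
      list(linear_pct = pd$linear$variance_explained_pct,
           ward_pct = pd$ward$variance_explained_pct,
           nn_cv_pct = pd$nn$variance_explained_pct,
           nn_in_sample_pct = pd$nn$in_sample_pct),
      file.path(out_dir, "variance_polypharmacy.json"),
      auto_unbox = TRUE, digits = NA)
    res$variance <- list(side_effects = se, polypharmacy = pd)
  }
  jsonlite::write_json(
    list(source = src, seed = seed, stages = stages,
         config_hash = .config_hash(if (is.character(config)) config
                                    else unclass(config))),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE)
  invisible(res)
}
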