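#' Read a long-format Cq table
#'
#' The canonical schema is tidy/long: one row per well and channel with
#' columns `sample_id`, `assay_id`, `channel` ("target" or "reference"),
#' `run`, `replicate`, `cq`, and optionally `template_mass` (ng,
#' calibration rows only). Dropouts may be encoded as an empty cell, `NA`
#' or the literal `Undetermined`; they parse to an absent Cq with the
#' `dropout` flag set. Comma- and tab-separated files are supported
#' (chosen by extension, or forced with `sep`).
#'
#' Validation is strict: unknown assay ids, Cq values outside (0, 45) and
#' duplicated `(sample, assay, run, replicate, channel)` keys are hard
#' errors naming the offending rows.
#'
#' @param path Path to the CSV/TSV file.
#' @param sep Optional field separator; default inferred from extension
#'   (".tsv"/".txt" = tab, otherwise comma).
#' @return data.frame of validated Cq records with a logical `dropout`
#'   column.
#' @export
read_cq_table <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- read.csv(path, sep = sep, colClasses = "character",
                  stringsAsFactors = FALSE)
  need <- c("sample_id", "assay_id", "channel", "run", "replicate", "cq")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  check_assay_ids(raw$assay_id)
  if (!all(raw$channel %in% c("target", "reference")))
    stop("channel must be 'target' or 'reference'")
  cq_raw <- trimws(raw$cq)
  dropout <- cq_raw == "" | is.na(cq_raw) |
    tolower(cq_raw) %in% c("undetermined", "na")
  cq <- suppressWarnings(as.numeric(cq_raw))
  bad_parse <- which(!dropout & is.na(cq))
  if (length(bad_parse))
    stop("unparseable Cq value(s) at data row(s): ",
         paste(head(bad_parse, 5), collapse = ", "))
  out_of_range <- which(!dropout & (cq <= 0 | cq >= 45))
  if (length(out_of_range))
    stop("Cq outside (0, 45) at data row(s): ",
         paste(head(out_of_range, 5), collapse = ", "))
  cq[dropout] <- NA_real_
  key <- paste(raw$sample_id, raw$assay_id, raw$run, raw$replicate,
               raw$channel)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop("duplicated (sample, assay, run, replicate, channel) key at ",
         "data rows ", paste(which(key == d), collapse = " and "),
         ": ", d)
  }
  out <- data.frame(sample_id = raw$sample_id, assay_id = raw$assay_id,
                    channel = raw$channel, run = as.integer(raw$run),
                    replicate = as.integer(raw$replicate), cq = cq,
                    dropout = dropout, stringsAsFactors = FALSE)
  if ("template_mass" %in% names(raw))
    out$template_mass <- suppressWarnings(as.numeric(raw$template_mass))
  out
}

#' Write a long-format Cq table
#'
#' Dropouts are written as `NA` in the `cq` column.
#'
#' @param cq Cq data.frame.
#' @param path Output path (CSV).
#' @return The path, invisibly.
#' @export
write_cq_table <- function(cq, path) {
  write.csv(cq, path, row.names = FALSE)
  invisible(path)
}

#' Convert a wide instrument export to the long Cq schema
#'
#' Accepts one row per well with paired channel columns `cq_target` and
#' `cq_reference` (plus `sample_id`, `assay_id`, `run`, `replicate`) and
#' stacks them into the canonical long format.
#'
#' @param wide data.frame in the wide per-well layout.
#' @return Long-format Cq data.frame.
#' @export
cq_from_wide <- function(wide) {
  need <- c("sample_id", "assay_id", "run", "replicate",
            "cq_target", "cq_reference")
  miss <- setdiff(need, names(wide))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  long <- rbind(
    data.frame(wide[c("sample_id", "assay_id", "run", "replicate")],
               channel = "reference", cq = wide$cq_reference,
               stringsAsFactors = FALSE),
    data.frame(wide[c("sample_id", "assay_id", "run", "replicate")],
               channel = "target", cq = wide$cq_target,
               stringsAsFactors = FALSE))
  long$dropout <- is.na(long$cq)
  long[order(long$sample_id, long$assay_id, long$run, long$replicate,
             long$channel), c("sample_id", "assay_id", "channel", "run",
                              "replicate", "cq", "dropout")] |>
    (\(d) { rownames(d) <- NULL; d })()
}

#' Write pipeline results to CSV files
#'
#' Writes three files into `dir`: `measured_gcns.csv` (per sample and
#' assay: mean, SD, CV%, CI, dropout counts, ambiguity), `integer_calls.csv`
#' (the integer-GCN calls with posteriors and flags) and `qc_metrics.csv`.
#' Empty inputs produce headers-only files. Numeric values are written
#' with full precision, so a write-read-write cycle is byte-identical.
#'
#' @param measured `samples` component of an `rccx_measured` (or NULL).
#' @param calls Integer-call data.frame from [call_gcn()] (or NULL).
#' @param metrics QC metric data.frame (or NULL).
#' @param dir Output directory; created if missing.
#' @return Named character vector of the file paths, invisibly.
#' @export
write_results <- function(measured = NULL, calls = NULL, metrics = NULL,
                          dir = ".") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  empty <- list(
    measured = data.frame(sample_id = character(), assay_id = character(),
                          n_wells = integer(), n_dropout = integer(),
                          mean = numeric(), sd = numeric(),
                          cv_percent = numeric(), ci_lo = numeric(),
                          ci_hi = numeric(), label = character(),
                          integer = numeric()),
    calls = data.frame(sample_id = character(), total = integer(),
                       C4A = integer(), C4B = integer(),
                       CYP21A1P = integer(), CYP21A2 = integer(),
                       HERV_del = integer(), HERV_ins = integer(),
                       BP = integer(), posterior = numeric(),
                       cv_pass = logical(), ambiguous = logical(),
                       consistency_pass = logical()),
    metrics = data.frame(metric = character(), assay_id = character(),
                         value = numeric()))
  if (inherits(measured, "rccx_measured")) measured <- measured$samples
  paths <- c(measured = file.path(dir, "measured_gcns.csv"),
             calls = file.path(dir, "integer_calls.csv"),
             metrics = file.path(dir, "qc_metrics.csv"))
  write.csv(if (is.null(measured)) empty$measured else measured,
            paths["measured"], row.names = FALSE)
  write.csv(if (is.null(calls)) empty$calls else calls,
            paths["calls"], row.names = FALSE)
  write.csv(if (is.null(metrics)) empty$metrics else metrics,
            paths["metrics"], row.names = FALSE)
  invisible(paths)
}

#' Read or write the pipeline configuration (YAML)
#'
#' One structured file holds the per-assay calibration offsets and
#' ambiguity half-width, the noise specification of the simulator, the
#' cohort design and the caller thresholds.
#'
#' @param path YAML file path.
#' @return For `read_config`, a list with elements `assay_config`,
#'   `noise`, `cohort`, `caller`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- default_config()
  for (nm in intersect(names(raw), names(cfg)))
    cfg[[nm]][names(raw[[nm]])] <- raw[[nm]]
  cfg$assay_config <- assay_config(
    offsets = unlist(cfg$assays$offsets),
    ambiguity_halfwidth = cfg$assays$ambiguity_halfwidth,
    reference_gene = cfg$assays$reference_gene)
  cfg$noise_spec <- do.call(noise_spec, cfg$noise)
  cfg$cohort_spec <- do.call(cohort_spec, c(
    cfg$cohort[c("n_samples", "wells_per_run", "runs")],
    list(quality_fractions = unlist(cfg$cohort$quality_fractions))))
  cfg
}

#' @rdname read_config
#' @param config Configuration list (as from [default_config()] or
#'   [read_config()]).
#' @export
write_config <- function(config, path) {
  keep <- intersect(names(config), c("assays", "noise", "cohort", "caller"))
  yaml::write_yaml(config[keep], path)
  invisible(path)
}

#' @rdname read_config
#' @export
default_config <- function() {
  ns <- noise_spec()
  cs <- cohort_spec()
  list(
    assays = list(
      offsets = as.list(setNames(numeric(7), rccx_assays())),
      ambiguity_halfwidth = 0.3,
      reference_gene = "RPPH1"),
    noise = list(base_ref_cq = ns$base_ref_cq, matrix_sd = ns$matrix_sd,
                 well_sd = ns$well_sd, run_sd = ns$run_sd,
                 asym_matrix_sd = ns$asym_matrix_sd,
                 degraded_extra_sd = ns$degraded_extra_sd,
                 degraded_bias = ns$degraded_bias),
    cohort = list(n_samples = cs$n_samples,
                  wells_per_run = cs$wells_per_run, runs = cs$runs,
                  quality_fractions = as.list(cs$quality_fractions)),
    caller = list(posterior_threshold = 0.95, regularization = 1e-6,
                  priors = "empirical"))
}
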