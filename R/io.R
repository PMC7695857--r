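# Break-list interchange: plain CSV and a minimal SDD-flavoured text
# format (comment header with provenance, then one whitespace-separated
# record per break). The full community SDD specification carries many
# optional fields this pipeline never populates, so only the essential
# ones are written.

#' Write breaks to CSV
#' @param breaks break data.frame (segment_id, bp_index, strand, source).
#' @param path output file.
#' @export
write_breaks_csv <- function(breaks, path) {
  write.csv(breaks[, c("segment_id", "bp_index", "strand", "source")],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read breaks from CSV
#' @param path CSV with columns segment_id, bp_index, strand, source.
#' @return break data.frame.
#' @export
read_breaks_csv <- function(path) {
  b <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("segment_id", "bp_index", "strand", "source")
  miss <- setdiff(need, names(b))
  if (length(miss))
    stop("break file lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  b[, need]
}

#' Write breaks as SDD-flavoured records
#'
#' Header lines `# key: value` (genome size, dose, config hash, record
#' count) followed by one `segment bp strand source` record per line.
#'
#' @param breaks break data.frame.
#' @param path output file.
#' @param genome_gbp,dose_gy,config_hash header metadata.
#' @export
write_breaks_sdd <- function(breaks, path, genome_gbp = NA, dose_gy = NA,
                             config_hash = NA) {
  header <- c(
    "# format: strandbreakr-sdd v1",
    paste0("# genome_gbp: ", genome_gbp),
    paste0("# dose_gy: ", dose_gy),
    paste0("# config_hash: ", config_hash),
    paste0("# n_records: ", nrow(breaks)),
    "# columns: segment_id bp_index strand source")
  records <- sprintf("%d %d %d %s", breaks$segment_id, breaks$bp_index,
                     breaks$strand, breaks$source)
  writeLines(c(header, records), path)
  invisible(path)
}

#' Read SDD-flavoured break records
#' @param path file from [write_breaks_sdd()].
#' @return list with `breaks` and `header` (named character).
#' @export
read_breaks_sdd <- function(path) {
  lines <- readLines(path)
  is_header <- startsWith(lines, "#")
  hdr <- lines[is_header]
  kv <- regmatches(hdr, regexec("^# ([^:]+): (.*)$", hdr))
  kv <- Filter(function(x) length(x) == 3L, kv)
  header <- setNames(vapply(kv, `[`, character(1), 3L),
                     vapply(kv, `[`, character(1), 2L))
  body <- lines[!is_header & nzchar(lines)]
  if (!length(body)) {
    breaks <- empty_breaks()
  } else {
    parts <- strsplit(trimws(body), "[[:space:]]+")
    bad <- which(vapply(parts, length, integer(1)) != 4L)
    if (length(bad))
      stop("malformed break record at line ",
           which(!is_header & nzchar(lines))[bad[1L]], " of ", path,
           call. = FALSE)
    m <- do.call(rbind, parts)
    suppressWarnings({
      breaks <- data.frame(segment_id = as.integer(m[, 1L]),
                           bp_index = as.integer(m[, 2L]),
                           strand = as.integer(m[, 3L]),
                           source = m[, 4L], stringsAsFactors = FALSE)
    })
    if (anyNA(breaks$segment_id) || anyNA(breaks$bp_index) ||
        anyNA(breaks$strand) ||
        !all(breaks$source %in% c("direct", "indirect")))
      stop("malformed break record in ", path, call. = FALSE)
  }
  list(breaks = breaks, header = header)
}

#' Write a yield summary (plus provenance) as JSON
#' @param summary a `yield_summary`.
#' @param path output file.
#' @param provenance optional named list (config hash, seeds, version).
#' @export
write_yield_json <- function(summary, path, provenance = NULL) {
  payload <- unclass(summary)
  if (!is.null(provenance)) payload$provenance <- provenance
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

provenance_block <- function(config) {
  list(config_hash = config_hash(config),
       seed = config$seed,
       package = "strandbreakr",
       version = as.character(utils::packageVersion("strandbreakr")))
}

#' Full pipeline run with outputs on disk
#'
#' Runs [simulate_damage()] and writes `breaks.csv`, `breaks.sdd.txt` and
#' `yields.json` (with a provenance block) into `out_dir`.
#'
#' @param config path to a JSON run config, a `run_config`, or NULL for
#'   defaults.
#' @param out_dir output directory (created if needed).
#' @param seed optional seed override.
#' @param histone_scavenging optional on/off override.
#' @return the `damage_run`, invisibly; file paths in `$files`.
#' @export
cmd_simulate <- function(config = NULL, out_dir = ".", seed = NULL,
                         histone_scavenging = NULL) {
  cfg <- if (is.character(config)) read_run_config(config)
         else if (is.null(config)) default_run_config()
         else validate_run_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (!is.null(histone_scavenging))
    cfg$geometry$histone_scavenging <- isTRUE(histone_scavenging)
  run <- simulate_damage(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- list(
    breaks_csv = file.path(out_dir, "breaks.csv"),
    breaks_sdd = file.path(out_dir, "breaks.sdd.txt"),
    yields_json = file.path(out_dir, "yields.json"))
  write_breaks_csv(run$breaks, files$breaks_csv)
  write_breaks_sdd(run$breaks, files$breaks_sdd,
                   genome_gbp = cfg$geometry$n_bp / 1e9,
                   dose_gy = run$counts$delivered_dose_gy,
                   config_hash = run$config_hash)
  prov <- provenance_block(cfg)
  prov$stage_counts <- run$counts
  write_yield_json(run$summary, files$yields_json, provenance = prov)
  run$files <- files
  invisible(run)
}

#' Classification-only run on a break file
#'
#' Reads a CSV or SDD-flavoured break list and classifies it exactly as
#' the in-pipeline path does.
#'
#' @param break_file CSV or `.sdd.txt` break file.
#' @param dose_gy,genome_gbp normalisation; for SDD input these default to
#'   the header values.
#' @param out optional JSON output path.
#' @return a `yield_summary`.
#' @export
cmd_classify <- function(break_file, dose_gy = NULL, genome_gbp = NULL,
                         out = NULL) {
  if (grepl("\\.csv$", break_file, ignore.case = TRUE)) {
    breaks <- read_breaks_csv(break_file)
  } else {
    sdd <- read_breaks_sdd(break_file)
    breaks <- sdd$breaks
    if (is.null(dose_gy)) dose_gy <- as.numeric(sdd$header[["dose_gy"]])
    if (is.null(genome_gbp))
      genome_gbp <- as.numeric(sdd$header[["genome_gbp"]])
  }
  if (is.null(dose_gy) || is.null(genome_gbp) || is.na(dose_gy) ||
      is.na(genome_gbp))
    stop("dose_gy and genome_gbp are required (not found in header)",
         call. = FALSE)
  summary <- classify_breaks(breaks, dose_gy, genome_gbp)
  if (!is.null(out)) write_yield_json(summary, out)
  summary
}

#' Repair-kinetics run with CSV outputs
#'
#' @param n_ncdsb,n_cdsb DSB counts per cell (or pass a `yield_summary`
#'   as `summary`).
#' @param summary optional `yield_summary` supplying the counts.
#' @param rates rate table or path to a JSON rate file; NULL for the
#'   default table.
#' @param dose_gy dose, Gy.
#' @param t_end_h,dt_out_h output grid (default 0-25 h at 0.1 h).
#' @param out_dir output directory for `trajectory.csv` and `foci.csv`
#'   (NULL to skip writing).
#' @return list with `trajectory` and `foci`.
#' @export
cmd_repair <- function(n_ncdsb = NULL, n_cdsb = NULL, summary = NULL,
                       rates = NULL, dose_gy = 1, t_end_h = 25,
                       dt_out_h = 0.1, out_dir = NULL) {
  if (!is.null(summary)) {
    n_ncdsb <- summary$n_ncdsb
    n_cdsb <- summary$n_cdsb
  }
  if (is.null(n_ncdsb) || is.null(n_cdsb))
    stop("provide n_ncdsb and n_cdsb or a yield summary", call. = FALSE)
  rates <- if (is.null(rates)) default_rate_table()
           else if (is.character(rates)) read_rate_table(rates)
           else validate_rate_table(rates)
  inputs <- repair_inputs(n_ncdsb, n_cdsb, dose_gy)
  traj <- simulate_repair(inputs, rates, t_end_h, dt_out_h)
  foci <- gamma_h2ax_curve(traj, rates)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(as.data.frame(traj), file.path(out_dir, "trajectory.csv"),
              row.names = FALSE, quote = FALSE)
    write.csv(as.data.frame(foci), file.path(out_dir, "foci.csv"),
              row.names = FALSE, quote = FALSE)
  }
  list(trajectory = traj, foci = foci)
}

#' Scavenging-protection experiment entry point
#'
#' @param mode "cell" or "plasmid".
#' @param seeds replicate seeds.
#' @param dose_gy dose per replicate.
#' @param n_bp fibre length.
#' @param out optional JSON output path for the aggregate table.
#' @return list with `on` and `off` `experiment_result`s.
#' @export
cmd_protect <- function(mode = "cell", seeds = 1:5, dose_gy = 1,
                        n_bp = 10000L, out = NULL) {
  plan <- experiment_plan(mode = mode, seeds = seeds, dose_gy = dose_gy,
                          n_bp = n_bp)
  res <- run_scavenging_experiment(plan)
  if (!is.null(out)) {
    payload <- list(
      on = res$on$aggregate, off = res$off$aggregate,
      provenance = list(config_hash = res$on$config_hash,
                        seeds = plan$seeds))
    jsonlite::write_json(payload, out, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", na = "null")
  }
  res
}

#' Degree-of-protection fit from a survival table
#'
#' @param table data.frame (or CSV path) with columns `concentration` and
#'   either `dp` or survival fractions `sf` plus a zero-concentration row
#'   (concentration 0 gives SF0).
#' @return the [fit_max_protection()] result.
#' @export
cmd_dpfit <- function(table) {
  if (is.character(table)) table <- read.csv(table)
  if (!"dp" %in% names(table)) {
    if (!all(c("concentration", "sf") %in% names(table)))
      stop("table needs `concentration` + `dp`, or `concentration` + `sf` ",
           "with a concentration-0 row", call. = FALSE)
    zero <- table$concentration == 0
    if (!any(zero)) stop("no zero-concentration row for SF0", call. = FALSE)
    sf0 <- table$sf[zero][1L]
    table <- table[!zero, , drop = FALSE]
    table$dp <- degree_of_protection(sf0, table$sf)
  }
  fit_max_protection(table$concentration, table$dp)
}
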