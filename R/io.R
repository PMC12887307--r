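# Interchange formats. All writers emit full-precision ("%.17g") numbers so
# write -> read round-trips are lossless; all readers validate the header
# and report offending columns/rows by name.

fmt_num <- function(x) sprintf("%.17g", x)

check_columns <- function(df, required, file) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stopf("%s: missing column(s): %s", file, paste(missing, collapse = ", "))
  }
}

check_numeric <- function(df, cols, file) {
  for (col in cols) {
    x <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(x) & !is.na(df[[col]]))
    if (length(bad)) {
      stopf("%s: non-numeric value in column '%s' at data row %d",
            file, col, bad[1])
    }
    if (anyNA(df[[col]])) {
      stopf("%s: missing value in column '%s' at data row %d",
            file, col, which(is.na(df[[col]]))[1])
    }
    df[[col]] <- x
  }
  df
}

#' Read / write pressure traces as CSV
#'
#' Column layout: `unit_id, t_seconds, pressure_hPa, temperature_C` with a
#' mandatory header; one file may hold many units.
#'
#' @param file path to the CSV.
#' @param light_on,photoperiod light schedule applied to every unit read.
#' @return `read_pressure_csv`: named list of `ces_pressure_trace` objects.
#' @export
read_pressure_csv <- function(file, light_on = 0, photoperiod = 12) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  check_columns(df, c("unit_id", "t_seconds", "pressure_hPa", "temperature_C"),
                file)
  df <- check_numeric(df, c("t_seconds", "pressure_hPa", "temperature_C"), file)
  traces <- lapply(split(df, df$unit_id), function(d) {
    d <- d[order(d$t_seconds), ]
    pressure_trace(d$unit_id[1], d$t_seconds, d$pressure_hPa, d$temperature_C,
                   light_on = light_on, photoperiod = photoperiod)
  })
  traces[unique(df$unit_id)]
}

#' @rdname read_pressure_csv
#' @param traces a `ces_pressure_trace` or list of them.
#' @export
write_pressure_csv <- function(traces, file) {
  if (inherits(traces, "ces_pressure_trace")) traces <- list(traces)
  rows <- lapply(traces, function(tr) {
    data.frame(unit_id = tr$unit_id, t_seconds = fmt_num(tr$t),
               pressure_hPa = fmt_num(tr$pressure),
               temperature_C = fmt_num(tr$temperature))
  })
  utils::write.csv(do.call(rbind, rows), file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read / write FT-ICR-MS peak lists as CSV
#'
#' Column layout: `mz, intensity`, one file per sample; the sample id is the
#' file name stem unless supplied.
#'
#' @param file path to the CSV.
#' @return `read_peaklist_csv`: data frame with `mz`, `intensity`, sorted by
#'   m/z, with the sample id attached as attribute `sample_id`.
#' @export
read_peaklist_csv <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  check_columns(df, c("mz", "intensity"), file)
  df <- check_numeric(df, c("mz", "intensity"), file)
  df <- df[order(df$mz), c("mz", "intensity")]
  rownames(df) <- NULL
  attr(df, "sample_id") <- sub("\\.[^.]*$", "", basename(file))
  df
}

#' @rdname read_peaklist_csv
#' @param peaks data frame with `mz` and `intensity`.
#' @export
write_peaklist_csv <- function(peaks, file) {
  check_columns(peaks, c("mz", "intensity"), "peak list")
  out <- data.frame(mz = fmt_num(peaks$mz), intensity = fmt_num(peaks$intensity))
  utils::write.csv(out, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read / write ASV tables as TSV
#'
#' Column layout: `asv_id`, `taxonomy` (semicolon-delimited ranks, genus in
#' the sixth field), then one integer column per sample.
#'
#' @param file path to the TSV.
#' @param metadata optional per-sample metadata to attach on read.
#' @return `read_asv_tsv`: a `ces_asv_table`.
#' @export
read_asv_tsv <- function(file, metadata = NULL) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE, check.names = FALSE)
  check_columns(df, c("asv_id", "taxonomy"), file)
  dup <- df$asv_id[duplicated(df$asv_id)]
  if (length(dup)) stopf("%s: duplicate asv_id '%s'", file, dup[1])
  sample_cols <- setdiff(names(df), c("asv_id", "taxonomy"))
  if (!length(sample_cols)) stopf("%s: no sample columns", file)
  df <- check_numeric(df, sample_cols, file)
  counts <- as.matrix(df[, sample_cols, drop = FALSE])
  rownames(counts) <- df$asv_id
  if (all(counts == round(counts))) storage.mode(counts) <- "integer"
  asv_table(counts, df$taxonomy, metadata)
}

#' @rdname read_asv_tsv
#' @param table a `ces_asv_table`.
#' @export
write_asv_tsv <- function(table, file) {
  stopifnot(inherits(table, "ces_asv_table"))
  out <- data.frame(asv_id = rownames(table$counts),
                    taxonomy = table$taxonomy,
                    table$counts, check.names = FALSE)
  utils::write.table(out, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Write a numeric matrix (distance matrix, PCoA coordinates, grids) as TSV
#' @param m matrix with dimnames.
#' @param file output path.
#' @param row_label header of the row-name column.
#' @export
write_matrix_tsv <- function(m, file, row_label = "id") {
  m <- as.matrix(m)
  out <- data.frame(rownames(m) %||% seq_len(nrow(m)), m, check.names = FALSE)
  names(out)[1] <- row_label
  utils::write.table(out, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Write results as JSON (full precision, scalars unboxed)
#' @param x list of results.
#' @param file output path.
#' @export
write_results_json <- function(x, file) {
  jsonlite::write_json(x, file, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(file)
}

#' Write a complete synthetic study bundle to disk
#'
#' Generates the three synthetic datasets and writes them in the interchange
#' formats (pressure CSV, per-sample peak-list CSVs with a manifest, ASV
#' TSV) together with JSON ground-truth files; everything round-trips
#' losslessly through the readers.
#'
#' @param dir output directory (created if needed).
#' @param pressure,dom,community the three scenario objects.
#' @return invisible list with the generated objects and file paths.
#' @export
gen_study_bundle <- function(dir,
                             pressure = pressure_scenario(),
                             dom = dom_scenario(),
                             community = community_scenario()) {
  dir.create(file.path(dir, "peaks"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), recursive = TRUE, showWarnings = FALSE)

  pexp <- gen_pressure_experiment(pressure)
  write_pressure_csv(c(pexp$traces, list(CONTROL = pexp$control)),
                     file.path(dir, "pressure.csv"))
  write_results_json(pexp$truth$cycles, file.path(dir, "truth", "pressure.json"))

  domx <- gen_dom_peaklists(dom)
  peak_files <- vapply(names(domx$peaklists), function(s) {
    write_peaklist_csv(domx$peaklists[[s]],
                       file.path(dir, "peaks", paste0(s, ".csv")))
  }, "")
  utils::write.csv(domx$samples, file.path(dir, "peaks", "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  write_results_json(domx$truth$samples, file.path(dir, "truth", "dom.json"))

  comm <- gen_asv_tables(community)
  write_asv_tsv(comm$table, file.path(dir, "asv_table.tsv"))
  utils::write.csv(comm$table$metadata, file.path(dir, "samples.csv"),
                   row.names = FALSE, quote = FALSE)
  write_results_json(
    list(trajectories = as.data.frame(comm$truth$trajectories),
         within_genus_split = as.data.frame(comm$truth$within_genus_split)),
    file.path(dir, "truth", "community.json")
  )

  invisible(list(
    pressure = pexp, dom = domx, community = comm,
    files = list(
      pressure = file.path(dir, "pressure.csv"),
      peaks = unname(peak_files),
      manifest = file.path(dir, "peaks", "manifest.csv"),
      asv_table = file.path(dir, "asv_table.tsv"),
      samples = file.path(dir, "samples.csv")
    )
  ))
}
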