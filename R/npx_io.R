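# -- NPX container -----------------------------------------------------------

#' Construct an NPX matrix object
#'
#' Wide container for one cohort's targeted-proteomics panel: a samples x
#' proteins matrix of NPX values (log2 scale) together with per-protein limits
#' of detection and per-sample plate and sample-type annotations. Bridge
#' samples are pooled plasma controls measured alongside the study samples and
#' are carried in the same matrix, distinguished by `sample_type`.
#'
#' @param values numeric matrix, samples in rows (rownames = sample ids),
#'   proteins in columns (colnames = assay ids). NPX on the log2 scale;
#'   missing cells allowed as `NA`.
#' @param lod named numeric vector of per-protein limits of detection, same
#'   log2 scale and same protein universe as `values`.
#' @param plate named character vector mapping each sample to its plate.
#' @param sample_type named character vector, `"study"` or `"bridge"` per
#'   sample.
#' @param cohort single string labelling the cohort.
#' @param panel optional named character vector of panel labels per protein.
#' @param qc_warn optional named logical vector; `TRUE` if any record of the
#'   sample carried a QC warning flag.
#' @return an object of class `npx_matrix`.
#' @export
npx_matrix <- function(values, lod, plate, sample_type, cohort,
                       panel = NULL, qc_warn = NULL) {
  stopifnot(is.matrix(values), is.numeric(values))
  samples <- rownames(values)
  proteins <- colnames(values)
  if (is.null(samples) || is.null(proteins))
    stop("values must have sample rownames and protein colnames")
  if (anyDuplicated(samples)) stop("duplicate sample ids")
  if (anyDuplicated(proteins)) stop("duplicate protein ids")
  if (!all(proteins %in% names(lod)))
    stop("lod missing for proteins: ",
         paste(setdiff(proteins, names(lod)), collapse = ", "))
  if (!all(samples %in% names(plate)))
    stop("plate missing for samples: ",
         paste(utils::head(setdiff(samples, names(plate))), collapse = ", "))
  if (!all(samples %in% names(sample_type)))
    stop("sample_type missing for some samples")
  if (!all(sample_type %in% c("study", "bridge")))
    stop("sample_type must be 'study' or 'bridge'")
  lod <- lod[proteins]
  if (any(!is.finite(lod))) stop("non-finite LOD")
  structure(list(
    values = values,
    lod = lod,
    plate = plate[samples],
    sample_type = sample_type[samples],
    cohort = as.character(cohort)[1],
    panel = if (!is.null(panel)) panel[proteins] else NULL,
    qc_warn = if (!is.null(qc_warn)) qc_warn[samples] else NULL
  ), class = "npx_matrix")
}

#' @export
print.npx_matrix <- function(x, ...) {
  cat(sprintf("<npx_matrix> cohort '%s': %d samples (%d study, %d bridge) x %d proteins\n",
              x$cohort, nrow(x$values), sum(x$sample_type == "study"),
              sum(x$sample_type == "bridge"), ncol(x$values)))
  cat(sprintf("  plates: %s\n", paste(sort(unique(x$plate)), collapse = ", ")))
  invisible(x)
}

#' @export
dim.npx_matrix <- function(x) dim(x$values)

#' Sample ids of a given type
#' @param x an `npx_matrix`
#' @param type `"study"` or `"bridge"`
#' @return character vector of sample ids
#' @export
npx_samples <- function(x, type = c("study", "bridge")) {
  type <- match.arg(type)
  names(x$sample_type)[x$sample_type == type]
}

#' Extract the value matrix, optionally restricted to one sample type
#' @param x an `npx_matrix`
#' @param type `"all"`, `"study"` or `"bridge"`
#' @return numeric matrix
#' @export
npx_values <- function(x, type = c("all", "study", "bridge")) {
  type <- match.arg(type)
  if (type == "all") return(x$values)
  x$values[npx_samples(x, type), , drop = FALSE]
}

#' Subset an NPX matrix by samples and/or proteins
#' @param x an `npx_matrix`
#' @param samples,proteins character vectors of ids to keep (default all)
#' @return an `npx_matrix`
#' @export
npx_subset <- function(x, samples = rownames(x$values),
                       proteins = colnames(x$values)) {
  npx_matrix(x$values[samples, proteins, drop = FALSE],
             x$lod[proteins], x$plate[samples], x$sample_type[samples],
             x$cohort,
             panel = if (!is.null(x$panel)) x$panel[proteins] else NULL,
             qc_warn = if (!is.null(x$qc_warn)) x$qc_warn[samples] else NULL)
}

# -- long-format ingest ------------------------------------------------------

.npx_long_cols <- c("SampleID", "Assay", "Panel", "NPX", "LOD",
                    "PlateID", "QC_Warning", "SampleType")

.detect_delim <- function(path) {
  line <- readLines(path, n = 1L)
  if (lengths(regmatches(line, gregexpr("\t", line))) >=
      lengths(regmatches(line, gregexpr(",", line)))) "\t" else ","
}

#' Read a long-format NPX export
#'
#' Reads a delimited long table (one row per sample x assay measurement, the
#' layout of vendor NPX exports) and pivots it into an [npx_matrix]. The
#' delimiter is auto-detected (comma vs tab) unless given. Sample and protein
#' identifiers are trimmed and sorted; duplicate (sample, protein) pairs are
#' rejected. Cells for which no record exists are stored as `NA` and excluded
#' pairwise downstream.
#'
#' Required columns: `SampleID, Assay, Panel, NPX, LOD, PlateID, QC_Warning,
#' SampleType`. `SampleType` is `study` or `bridge`; `QC_Warning` is `pass`
#' or `warn`. Bridge samples are ingested regardless of QC flag; the number
#' of flagged bridge records is reported via a message.
#'
#' @param path file path of the delimited table.
#' @param cohort_label cohort name stored on the result.
#' @param delim optional explicit delimiter (`","` or `"\t"`).
#' @return an `npx_matrix`; attribute `n_records` carries the ingested row
#'   count.
#' @export
read_npx_long <- function(path, cohort_label, delim = NULL) {
  if (is.null(delim)) delim <- .detect_delim(path)
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          quote = "\"", comment.char = "")
  missing <- setdiff(.npx_long_cols, names(df))
  if (length(missing))
    stop("schema error: missing required column(s): ",
         paste(missing, collapse = ", "))
  df$SampleID <- trimws(df$SampleID)
  df$Assay <- trimws(df$Assay)
  key <- paste(df$SampleID, df$Assay, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    stop("integrity error: duplicate (sample, protein) pairs: ",
         paste(utils::head(gsub("\r", "/", dup), 5), collapse = ", "))
  }
  if (!all(is.finite(df$NPX))) stop("non-finite NPX values")
  if (!all(is.finite(df$LOD))) stop("non-finite LOD values")
  if (!all(df$SampleType %in% c("study", "bridge")))
    stop("SampleType must be 'study' or 'bridge'")

  samples <- sort(unique(df$SampleID))
  proteins <- sort(unique(df$Assay))
  values <- matrix(NA_real_, length(samples), length(proteins),
                   dimnames = list(samples, proteins))
  values[cbind(match(df$SampleID, samples), match(df$Assay, proteins))] <- df$NPX

  # per-protein LOD: exports occasionally disagree across plates; take median
  lod <- vapply(split(df$LOD, df$Assay), function(v) {
    if (length(unique(v)) > 1L) stats::median(v) else v[1]
  }, numeric(1))[proteins]

  first <- !duplicated(df$SampleID)
  plate <- stats::setNames(as.character(df$PlateID[first]), df$SampleID[first])
  stype <- stats::setNames(df$SampleType[first], df$SampleID[first])
  qc <- vapply(split(df$QC_Warning == "warn", df$SampleID), any, logical(1))
  panel <- stats::setNames(df$Panel[!duplicated(df$Assay)],
                           df$Assay[!duplicated(df$Assay)])

  n_bridge_warn <- sum(df$QC_Warning == "warn" & df$SampleType == "bridge")
  if (n_bridge_warn > 0)
    message(n_bridge_warn, " bridge-sample records carried a QC warning; ingested regardless")

  out <- npx_matrix(values, lod, plate, stype, cohort_label,
                    panel = panel, qc_warn = qc)
  attr(out, "n_records") <- nrow(df)
  out
}

#' Write an NPX matrix back to the long export layout
#'
#' Inverse of [read_npx_long()]: one row per non-missing cell, samples and
#' proteins in sorted order, so `read(write(read(x)))` round-trips.
#'
#' @param x an `npx_matrix`
#' @param path output file path
#' @param delim field delimiter (default comma)
#' @return `path`, invisibly
#' @export
write_npx_long <- function(x, path, delim = ",") {
  samples <- sort(rownames(x$values))
  proteins <- sort(colnames(x$values))
  v <- x$values[samples, proteins, drop = FALSE]
  keep <- !is.na(v)
  idx <- which(keep, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  df <- data.frame(
    SampleID = samples[idx[, 1]],
    Assay = proteins[idx[, 2]],
    Panel = if (!is.null(x$panel)) unname(x$panel[proteins[idx[, 2]]]) else "panel1",
    NPX = v[idx],
    LOD = unname(x$lod[proteins[idx[, 2]]]),
    PlateID = unname(x$plate[samples[idx[, 1]]]),
    QC_Warning = if (!is.null(x$qc_warn))
      ifelse(x$qc_warn[samples[idx[, 1]]], "warn", "pass") else "pass",
    SampleType = unname(x$sample_type[samples[idx[, 1]]]),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = delim, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pair two cohorts on their common protein panel
#'
#' Returns the intersection of the two protein universes together with the
#' proteins private to each cohort. Values are not touched; downstream
#' cross-cohort analyses subset to `common`.
#'
#' @param a,b `npx_matrix` objects
#' @return list with `common`, `only_a`, `only_b` (sorted character vectors)
#'   and the untouched inputs `a`, `b`.
#' @export
merge_cohorts <- function(a, b) {
  stopifnot(inherits(a, "npx_matrix"), inherits(b, "npx_matrix"))
  pa <- colnames(a$values); pb <- colnames(b$values)
  if (length(pa) == 0 || length(pb) == 0) stop("empty cohort matrix")
  common <- sort(intersect(pa, pb))
  if (length(common) == 0)
    stop("cohorts share no proteins; cannot merge")
  list(common = common,
       only_a = sort(setdiff(pa, pb)),
       only_b = sort(setdiff(pb, pa)),
       a = a, b = b)
}

# -- sample metadata ---------------------------------------------------------

#' Default metadata codebook
#'
#' Declares the accepted levels for each categorical metadata variable and a
#' map from common aliases to canonical levels (e.g. `"F"` to `"female"`).
#'
#' @return named list; each element has `levels` and optionally `map`.
#' @export
default_codebook <- function() {
  list(
    sex = list(levels = c("male", "female"),
               map = c(M = "male", m = "male", F = "female", f = "female",
                       Male = "male", Female = "female")),
    season = list(levels = c("dry", "rainy"),
                  map = c(Dry = "dry", Rainy = "rainy", wet = "rainy")),
    residency = list(levels = c("urban", "rural"),
                     map = c(Urban = "urban", Rural = "rural")),
    toilet = list(levels = c("pit_latrine", "water_closet")),
    cooking_fuel = list(levels = c("smoky", "non_smoky")),
    animal_exposure = list(levels = c("yes", "no")),
    antibiotics_past_year = list(levels = c("none", "1-3", ">3")),
    water_source = list(levels = c("tap", "other"))
  )
}

#' Read and validate per-sample metadata
#'
#' Reads a delimited metadata table (one row per participant) and validates
#' categorical variables against a codebook. Aliases are mapped to canonical
#' levels; values outside the codebook raise a warning and are kept with the
#' explicit level `"unknown"`. Numeric invariants (age > 0, BMI > 0 when
#' present) are enforced.
#'
#' @param path metadata file (CSV/TSV, delimiter auto-detected).
#' @param codebook codebook list as produced by [default_codebook()].
#' @param delim optional explicit delimiter.
#' @return `data.frame` with one row per sample, `sample_id` column first.
#' @export
read_metadata <- function(path, codebook = default_codebook(), delim = NULL) {
  if (is.null(delim)) delim <- .detect_delim(path)
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!"sample_id" %in% names(df)) stop("metadata must have a sample_id column")
  validate_metadata(df, codebook)
}

#' Validate an in-memory metadata table against a codebook
#' @param df data.frame with `sample_id` and metadata columns
#' @param codebook see [default_codebook()]
#' @return validated data.frame
#' @export
validate_metadata <- function(df, codebook = default_codebook()) {
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in metadata")
  if ("age" %in% names(df)) {
    df$age <- as.numeric(df$age)
    bad <- which(!is.na(df$age) & df$age <= 0)
    if (length(bad))
      stop("invalid age (must be > 0) for sample(s): ",
           paste(df$sample_id[bad], collapse = ", "))
  }
  if ("bmi" %in% names(df)) {
    df$bmi <- as.numeric(df$bmi)
    bad <- which(!is.na(df$bmi) & df$bmi <= 0)
    if (length(bad))
      stop("invalid bmi (must be > 0) for sample(s): ",
           paste(df$sample_id[bad], collapse = ", "))
  }
  for (v in intersect(names(codebook), names(df))) {
    cb <- codebook[[v]]
    x <- as.character(df[[v]])
    if (!is.null(cb$map)) {
      hit <- x %in% names(cb$map)
      x[hit] <- cb$map[x[hit]]
    }
    unknown <- !is.na(x) & !(x %in% cb$levels)
    if (any(unknown)) {
      warning(sprintf("metadata '%s': %d value(s) outside codebook (%s); kept as 'unknown'",
                      v, sum(unknown),
                      paste(utils::head(unique(x[unknown]), 3), collapse = ", ")))
      x[unknown] <- "unknown"
    }
    df[[v]] <- x
  }
  df
}

#' Align metadata rows to the study samples of an NPX matrix
#' @param x an `npx_matrix`
#' @param meta metadata data.frame with `sample_id`
#' @return metadata subset in the order of the study samples
#' @export
align_metadata <- function(x, meta) {
  ids <- npx_samples(x, "study")
  hit <- ids %in% meta$sample_id
  if (!any(hit)) stop("metadata shares no sample ids with the NPX matrix")
  if (!all(hit))
    warning(sum(!hit), " study sample(s) without metadata dropped from join")
  meta[match(ids[hit], meta$sample_id), , drop = FALSE]
}
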