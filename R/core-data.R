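# Domain objects: the fixed audiometric frequency grid, the ADNSHL gene
# panel, audiograms, and patient records (bags of audiograms).

#' Audiometric frequency grid
#'
#' The ten standard pure-tone air-conduction frequencies spanning 125 Hz to
#' 8000 Hz, including the half-octave interludes at 1500, 3000 and 6000 Hz.
#' All feature vectors, audioprofiles and surface fits index thresholds on
#' this grid.
#'
#' @return Integer vector of 10 frequencies in Hz, strictly increasing.
#' @export
#' @examples
#' freq_grid()
freq_grid <- function() {
  c(125L, 250L, 500L, 1000L, 1500L, 2000L, 3000L, 4000L, 6000L, 8000L)
}

# dB HL limits of clinical audiometers; thresholds outside are invalid and
# imputed/fitted values are clamped into this range.
DB_RANGE <- c(-10, 130)

#' ADNSHL gene panel
#'
#' The 23-gene autosomal dominant nonsyndromic hearing loss panel used for
#' ranking. The first eleven symbols are the well-characterized audioprofile
#' genes (WFS1, ACTG1, COCH, KCNQ4, MYO7A, EYA4, MYO6, TECTA, COL11A2,
#' GSDME, POU4F3); the remaining slots default to further established ADNSHL
#' genes and may be replaced, keeping the panel size at 23.
#'
#' @param genes Optional character vector of exactly 23 unique gene symbols
#'   to use instead of the default panel.
#' @return Character vector of 23 gene symbols (ordered; order defines
#'   deterministic tie-breaking in rankings).
#' @export
gene_panel <- function(genes = NULL) {
  if (is.null(genes)) {
    genes <- c(
      "WFS1", "ACTG1", "COCH", "KCNQ4", "MYO7A", "EYA4", "MYO6", "TECTA",
      "COL11A2", "GSDME", "POU4F3",
      "TMC1", "MYH14", "MYH9", "DIAPH1", "CCDC50", "GRHL2", "TJP2",
      "P2RX2", "SLC17A8", "OSBPL2", "TBC1D24", "MIR96"
    )
  }
  genes <- as.character(genes)
  if (length(genes) != 23L || anyDuplicated(genes)) {
    stop("gene panel must contain exactly 23 unique symbols")
  }
  genes
}

#' Construct an audiogram
#'
#' One hearing test: a patient's age and partial map of pure-tone thresholds
#' on the standard frequency grid.
#'
#' @param patient_id,audiogram_id Opaque identifier strings.
#' @param age Age in years at testing (non-negative real).
#' @param thresholds Named numeric vector of thresholds in dB HL; names are
#'   grid frequencies in Hz (see [freq_grid()]). Missing frequencies are
#'   simply absent (or `NA`).
#' @param region Optional region-of-origin label (`NA` if unknown).
#' @param gene Optional causative-gene symbol (`NA` if unlabeled).
#' @return An object of class `"audiogram"`.
#' @export
audiogram <- function(patient_id, audiogram_id, age, thresholds,
                      region = NA_character_, gene = NA_character_) {
  thr <- thresholds[!is.na(thresholds)]
  structure(
    list(
      patient_id = as.character(patient_id),
      audiogram_id = as.character(audiogram_id),
      age = as.numeric(age),
      thresholds = thr,
      region = as.character(region),
      gene = as.character(gene)
    ),
    class = "audiogram"
  )
}

#' Construct a patient record
#'
#' A "bag" of one or more audiograms sharing a patient id, optionally
#' labeled with the causative gene. Patients with a single audiogram are
#' routed to the single-instance classifier, patients with repeated
#' audiograms to the multi-instance classifier.
#'
#' @param patient_id Identifier shared by all member audiograms.
#' @param audiograms Non-empty list of [audiogram()] objects.
#' @param gene Optional gene label for the patient.
#' @return An object of class `"patient_record"`.
#' @export
patient_record <- function(patient_id, audiograms, gene = NA_character_) {
  structure(
    list(
      patient_id = as.character(patient_id),
      audiograms = audiograms,
      gene = as.character(gene)
    ),
    class = "patient_record"
  )
}

#' @export
print.audiogram <- function(x, ...) {
  cat(sprintf(
    "<audiogram %s> patient %s, age %.1f, %d/%d thresholds%s\n",
    x$audiogram_id, x$patient_id, x$age, length(x$thresholds),
    length(freq_grid()),
    if (is.na(x$gene)) "" else paste0(", gene ", x$gene)
  ))
  invisible(x)
}

#' @export
print.patient_record <- function(x, ...) {
  cat(sprintf(
    "<patient_record %s> %d audiogram(s)%s\n",
    x$patient_id, length(x$audiograms),
    if (is.na(x$gene)) "" else paste0(", gene ", x$gene)
  ))
  invisible(x)
}

# Column order of the on-disk CSV schema (one row per audiogram).
csv_columns <- function() {
  c("patient_id", "audiogram_id", "age", "region", "gene",
    paste0("thr_", freq_grid()))
}

#' Read an audiogram dataset
#'
#' Reads a comma-delimited file with one row per audiogram (columns
#' `patient_id, audiogram_id, age, region, gene, thr_125, ..., thr_8000`,
#' missing thresholds as empty cells) and groups rows into patient records.
#' Within a patient, audiograms are ordered by age ascending, ties by
#' audiogram id.
#'
#' @param path Path to a CSV file in the schema written by
#'   [write_audiograms()].
#' @return List of [patient_record()] objects (possibly empty).
#' @export
read_audiograms <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  missing_cols <- setdiff(csv_columns(), names(df))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0L) return(list())
  if (anyDuplicated(df$audiogram_id)) {
    dup <- unique(df$audiogram_id[duplicated(df$audiogram_id)])
    stop("duplicate audiogram_id: ", paste(dup, collapse = ", "))
  }
  age <- suppressWarnings(as.numeric(df$age))
  bad <- which(is.na(age) | age < 0)
  if (length(bad)) {
    stop("malformed age in data row(s): ", paste(bad, collapse = ", "))
  }
  thr_cols <- paste0("thr_", freq_grid())
  thr <- matrix(NA_real_, nrow(df), length(thr_cols))
  for (j in seq_along(thr_cols)) {
    raw <- df[[thr_cols[j]]]
    present <- !is.na(raw) & nzchar(trimws(raw))
    val <- suppressWarnings(as.numeric(raw[present]))
    if (anyNA(val)) {
      stop("malformed threshold in data row(s): ",
           paste(which(present)[is.na(val)], collapse = ", "))
    }
    thr[present, j] <- val
  }
  colnames(thr) <- as.character(freq_grid())

  blank_na <- function(x) ifelse(nzchar(trimws(x)), x, NA_character_)
  auds <- lapply(seq_len(nrow(df)), function(i) {
    audiogram(df$patient_id[i], df$audiogram_id[i], age[i],
              thr[i, ], blank_na(df$region[i]), blank_na(df$gene[i]))
  })
  split_idx <- split(seq_along(auds), factor(df$patient_id,
                                             levels = unique(df$patient_id)))
  lapply(split_idx, function(idx) {
    members <- auds[idx]
    ord <- order(vapply(members, `[[`, 0, "age"),
                 vapply(members, `[[`, "", "audiogram_id"))
    members <- members[ord]
    genes <- unique(stats::na.omit(vapply(members, `[[`, "", "gene")))
    patient_record(
      members[[1L]]$patient_id, members,
      gene = if (length(genes) == 1L) genes else NA_character_
    )
  }) |> unname()
}

#' Write an audiogram dataset
#'
#' Inverse of [read_audiograms()]: one CSV row per audiogram, missing
#' thresholds as empty cells. Reading the written file reproduces the
#' records field for field.
#'
#' @param records List of patient records.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_audiograms <- function(records, path) {
  grid <- freq_grid()
  rows <- lapply(records, function(rec) {
    do.call(rbind, lapply(rec$audiograms, function(a) {
      thr <- rep(NA_real_, length(grid))
      names(thr) <- as.character(grid)
      thr[names(a$thresholds)] <- a$thresholds
      df <- data.frame(
        patient_id = a$patient_id, audiogram_id = a$audiogram_id,
        age = a$age, region = a$region, gene = a$gene,
        stringsAsFactors = FALSE
      )
      for (j in seq_along(grid)) df[[paste0("thr_", grid[j])]] <- thr[j]
      df
    }))
  })
  out <- if (length(rows)) do.call(rbind, rows) else {
    as.data.frame(stats::setNames(
      rep(list(character(0)), length(csv_columns())), csv_columns()
    ))
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Validate a patient record
#'
#' Checks the structural invariants of a record and its member audiograms:
#' shared patient id, gene-label consistency, at least 3 observed thresholds
#' per audiogram, thresholds within the audiometer range and on the
#' frequency grid, non-negative ages. Validation never raises; it reports.
#'
#' @param record A [patient_record()].
#' @return Character vector of violation descriptions (empty if valid).
#' @export
validate_record <- function(record) {
  v <- character(0)
  grid <- as.character(freq_grid())
  if (!length(record$audiograms)) {
    return("audiograms: record contains no audiograms")
  }
  for (a in record$audiograms) {
    id <- a$audiogram_id
    if (!identical(a$patient_id, record$patient_id)) {
      v <- c(v, sprintf("patient_id: audiogram %s has id %s != record %s",
                        id, a$patient_id, record$patient_id))
    }
    if (is.na(a$age) || a$age < 0) {
      v <- c(v, sprintf("age: audiogram %s has invalid age", id))
    }
    obs <- a$thresholds
    if (length(obs) < 3L) {
      v <- c(v, sprintf(
        "thresholds: audiogram %s has %d observed values (minimum 3)",
        id, length(obs)))
    }
    off <- setdiff(names(obs), grid)
    if (length(off)) {
      v <- c(v, sprintf("thresholds: audiogram %s has off-grid frequency %s",
                        id, paste(off, collapse = ",")))
    }
    out_of_range <- obs < DB_RANGE[1] | obs > DB_RANGE[2]
    if (any(out_of_range)) {
      v <- c(v, sprintf(
        "thresholds: audiogram %s value %g dB at %s Hz outside [%g, %g]",
        id, obs[out_of_range][1], names(obs)[out_of_range][1],
        DB_RANGE[1], DB_RANGE[2]))
    }
    if (!is.na(record$gene) && !is.na(a$gene) &&
        !identical(a$gene, record$gene)) {
      v <- c(v, sprintf("gene: audiogram %s labeled %s != record label %s",
                        id, a$gene, record$gene))
    }
  }
  v
}

# Flatten records to per-audiogram metadata + list of audiograms.
# Used internally by most model-fitting code.
flatten_records <- function(records) {
  auds <- unlist(lapply(records, `[[`, "audiograms"), recursive = FALSE)
  rec_gene <- unlist(lapply(records, function(r) {
    rep(r$gene, length(r$audiograms))
  }))
  data_gene <- vapply(auds, `[[`, "", "gene")
  list(
    audiograms = auds,
    patient_id = vapply(auds, `[[`, "", "patient_id"),
    audiogram_id = vapply(auds, `[[`, "", "audiogram_id"),
    age = vapply(auds, `[[`, 0, "age"),
    gene = ifelse(is.na(data_gene), rec_gene, data_gene),
    region = vapply(auds, `[[`, "", "region")
  )
}
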