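SEGMENT_LABELS <- c("unlabeled", "S1", "systole", "S2", "diastole")
SEGMENT_CODES <- c(unlabeled = 0L, S1 = 1L, systole = 2L, S2 = 3L, diastole = 4L)

#' Segment table of labeled cardiac-cycle intervals
#'
#' Rows of `(start, end, label)` in seconds, half-open `[start, end)`,
#' sorted by start and non-overlapping. Labels are `S1`, `systole`, `S2`,
#' `diastole` or `unlabeled`.
#'
#' @param start,end Numeric vectors of segment boundaries in seconds.
#' @param label Character vector of segment labels.
#' @return A data frame with class `segment_table`.
#' @export
segment_table <- function(start = numeric(), end = numeric(), label = character()) {
  if (length(start) != length(end) || length(start) != length(label)) {
    stop("start, end and label must have equal length")
  }
  start <- as.numeric(start)
  end <- as.numeric(end)
  label <- as.character(label)
  if (length(start)) {
    if (any(!label %in% SEGMENT_LABELS)) {
      stop("unknown segment label(s): ",
           paste(unique(label[!label %in% SEGMENT_LABELS]), collapse = ", "))
    }
    if (any(start < 0)) stop("segment start times must be >= 0")
    if (any(end <= start)) stop("each segment must satisfy start < end")
    o <- order(start)
    start <- start[o]; end <- end[o]; label <- label[o]
    if (length(start) > 1L && any(start[-1L] < end[-length(end)] - 1e-12)) {
      stop("segments overlap")
    }
  }
  structure(
    data.frame(start = start, end = end, label = label,
               stringsAsFactors = FALSE),
    class = c("segment_table", "data.frame")
  )
}

#' Read a segmentation TSV
#'
#' Parses a 3-column tab-separated file of `start  end  code` rows, where the
#' integer code is 0 = unlabeled, 1 = S1, 2 = systole, 3 = S2, 4 = diastole.
#'
#' @param path Path to a TSV file.
#' @return A [segment_table].
#' @export
read_segment_tsv <- function(path) {
  if (!file.exists(path)) stop("TSV file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(segment_table())
  start <- end <- numeric(length(lines))
  label <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) != 3L) {
      stop(sprintf("%s line %d: expected 3 tab-separated fields", path, i))
    }
    s <- suppressWarnings(as.numeric(fields[1]))
    e <- suppressWarnings(as.numeric(fields[2]))
    code <- suppressWarnings(as.integer(fields[3]))
    if (is.na(s) || is.na(e)) {
      stop(sprintf("%s line %d: non-numeric start/end", path, i))
    }
    if (is.na(code) || !code %in% SEGMENT_CODES) {
      stop(sprintf("%s line %d: unknown segment code '%s'", path, i, fields[3]))
    }
    if (e <= s) {
      stop(sprintf("%s line %d: end <= start", path, i))
    }
    start[i] <- s; end[i] <- e
    label[i] <- names(SEGMENT_CODES)[match(code, SEGMENT_CODES)]
  }
  tryCatch(
    segment_table(start, end, label),
    error = function(err) stop(sprintf("%s: %s", path, conditionMessage(err)))
  )
}

#' Write a segmentation TSV
#'
#' Inverse of [read_segment_tsv()].
#'
#' @param segments A [segment_table].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segment_tsv <- function(segments, path) {
  codes <- SEGMENT_CODES[segments$label]
  lines <- sprintf("%.6f\t%.6f\t%d", segments$start, segments$end, codes)
  writeLines(lines, path)
  invisible(path)
}

MURMUR_LEVELS <- c("Present", "Unknown", "Absent")

#' Patient record
#'
#' @param patient_id Identifier string.
#' @param murmur Murmur label: `"Present"`, `"Unknown"` or `"Absent"`.
#' @param recordings List of [pcg_recording] objects (may be empty before
#'   audio is attached).
#' @param demographics Named character list of pass-through metadata.
#' @return An object of class `patient_record`.
#' @export
patient_record <- function(patient_id, murmur, recordings = list(),
                           demographics = list()) {
  murmur <- match.arg(as.character(murmur), MURMUR_LEVELS)
  structure(
    list(
      patient_id = as.character(patient_id),
      murmur = murmur,
      recordings = recordings,
      demographics = demographics
    ),
    class = "patient_record"
  )
}

#' @export
print.patient_record <- function(x, ...) {
  cat(sprintf("<patient_record> %s  murmur=%s  %d recording(s)\n",
              x$patient_id, x$murmur, length(x$recordings)))
  invisible(x)
}

#' Read a patient metadata text file
#'
#' Parses `key: value` lines. A `Murmur:` key with value Present/Unknown/Absent
#' (case-insensitive) is required; every other key is preserved verbatim in the
#' demographics map. A `Patient:` key, when present, supplies the patient id,
#' else the file stem is used.
#'
#' @param path Path to a metadata `.txt` file.
#' @return A [patient_record] without audio attached.
#' @export
read_patient_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  keys <- character(0); vals <- character(0)
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(m) != 3L) stop("malformed metadata line (need 'key: value'): ", ln)
    keys <- c(keys, trimws(m[2])); vals <- c(vals, trimws(m[3]))
  }
  mi <- which(tolower(keys) == "murmur")
  if (!length(mi)) stop("metadata file has no Murmur entry: ", path)
  raw <- tolower(vals[mi[1]])
  idx <- match(raw, tolower(MURMUR_LEVELS))
  if (is.na(idx)) stop("invalid murmur label '", vals[mi[1]], "' in ", path)
  pi_ <- which(tolower(keys) == "patient")
  pid <- if (length(pi_)) vals[pi_[1]] else sub("\\.txt$", "", basename(path))
  keep <- setdiff(seq_along(keys), c(mi[1], if (length(pi_)) pi_[1]))
  demo <- as.list(vals[keep])
  names(demo) <- keys[keep]
  patient_record(pid, MURMUR_LEVELS[idx], demographics = demo)
}

#' Write a patient metadata text file
#'
#' @param patient A [patient_record].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_patient_metadata <- function(patient, path) {
  lines <- c(
    sprintf("Patient: %s", patient$patient_id),
    sprintf("Murmur: %s", patient$murmur)
  )
  if (length(patient$demographics)) {
    lines <- c(lines, sprintf("%s: %s", names(patient$demographics),
                              unlist(patient$demographics)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Split specification
#'
#' @param train_fraction Fraction of patients assigned to the training split.
#' @param seed Integer seed making the split deterministic.
#' @return A list with class `split_spec`.
#' @export
split_spec <- function(train_fraction = 0.8, seed = 1L) {
  stopifnot_scalar_number(train_fraction, "train_fraction")
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("`train_fraction` must be in (0, 1)")
  }
  structure(list(train_fraction = train_fraction, seed = as.integer(seed)),
            class = "split_spec")
}

#' Stratified patient-level train/validation split
#'
#' Splits a patient list into train and validation sets, stratified by murmur
#' label, at the patient level (all recordings of a patient stay together).
#' Per-class training counts are allocated by the largest-remainder method so
#' that each class's train fraction is within one patient of
#' `round(train_fraction * class size)`; patients are shuffled within class by
#' the seeded RNG, with ties broken by lexicographic patient id.
#'
#' @param patients List of [patient_record] objects.
#' @param spec A [split_spec].
#' @return A list with elements `train` and `validation` (lists of patients).
#' @export
stratified_split <- function(patients, spec = split_spec()) {
  if (!length(patients)) stop("`patients` must be non-empty")
  ids <- vapply(patients, function(p) p$patient_id, character(1))
  labs <- vapply(patients, function(p) p$murmur, character(1))
  # canonical order before shuffling so the split depends only on ids + seed
  ord <- order(ids)
  patients <- patients[ord]; ids <- ids[ord]; labs <- labs[ord]
  classes <- intersect(MURMUR_LEVELS, unique(labs))
  n_class <- vapply(classes, function(cl) sum(labs == cl), numeric(1))
  total_train <- round(spec$train_fraction * length(patients))
  quota <- spec$train_fraction * n_class
  base <- floor(quota)
  rem <- total_train - sum(base)
  if (rem > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  } else if (rem < 0) {
    cut <- order(quota - base, decreasing = FALSE)
    take <- which(base[cut] > 0)[seq_len(-rem)]
    base[cut[take]] <- base[cut[take]] - 1L
  }
  train_idx <- integer(0)
  with_seed(spec$seed, {
    for (k in seq_along(classes)) {
      members <- which(labs == classes[k])
      shuffled <- members[sample.int(length(members))]
      train_idx <- c(train_idx, shuffled[seq_len(base[k])])
    }
  })
  train_idx <- sort(train_idx)
  list(
    train = patients[train_idx],
    validation = patients[setdiff(seq_along(patients), train_idx)]
  )
}
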