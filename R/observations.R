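#' @keywords internal
AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Canonical observation table columns, in canonical order. `modifications`
# is a compact string: ';'-separated "<pos>:<name>" entries where <pos> is a
# 1-based residue index or "N-term"/"C-term"; empty string means none.
OBS_COLUMNS <- c(
  "sequence", "modifications", "precursor_accession", "abundance",
  "quality", "rt_min", "mz", "subject_id", "group", "condition",
  "culture_rep", "tech_rep", "is_decoy"
)

MOD_NAMES <- c("oxidation", "pyro-glu", "acetylation", "amidation")

#' Parse a modification string into a tibble
#'
#' @param x A single modification string, e.g. `"2:oxidation;N-term:acetylation"`.
#' @return Tibble with columns `position` (character) and `name`.
#' @export
parse_modifications <- function(x) {
  if (is.na(x) || !nzchar(x)) {
    return(tibble::tibble(position = character(), name = character()))
  }
  parts <- strsplit(x, ";", fixed = TRUE)[[1]]
  bits <- strsplit(parts, ":", fixed = TRUE)
  bad <- lengths(bits) != 2
  if (any(bad)) {
    abort(sprintf("malformed modification entry: '%s'", parts[bad][1]))
  }
  tibble::tibble(
    position = trimws(vapply(bits, `[`, "", 1)),
    name = trimws(vapply(bits, `[`, "", 2))
  )
}

#' Format a modification tibble back into the compact string form
#'
#' @param mods Tibble with columns `position`, `name`.
#' @return A single string (empty if no modifications).
#' @export
format_modifications <- function(mods) {
  if (nrow(mods) == 0) return("")
  paste(paste(mods$position, mods$name, sep = ":"), collapse = ";")
}

# Validate one modification list against its peptide sequence. Returns a
# character vector of problems (empty when valid).
check_modifications <- function(sequence, mods) {
  problems <- character()
  n <- nchar(sequence)
  for (i in seq_len(nrow(mods))) {
    pos <- mods$position[i]
    name <- mods$name[i]
    if (!name %in% MOD_NAMES) {
      problems <- c(problems, sprintf("unknown modification '%s'", name))
      next
    }
    at_terminus <- pos %in% c("N-term", "C-term")
    idx <- if (at_terminus) {
      if (pos == "N-term") 1L else n
    } else {
      suppressWarnings(as.integer(pos))
    }
    if (is.na(idx) || idx < 1L || idx > n) {
      problems <- c(problems, sprintf(
        "modification position '%s' outside peptide of length %d", pos, n
      ))
      next
    }
    res <- substr(sequence, idx, idx)
    ok <- switch(name,
      "oxidation" = res == "M",
      "pyro-glu" = idx == 1L && res %in% c("Q", "E"),
      "acetylation" = idx == 1L,
      "amidation" = idx == n
    )
    if (!ok) {
      problems <- c(problems, sprintf(
        "modification '%s' incompatible with residue %s at position %d",
        name, res, idx
      ))
    }
  }
  problems
}

#' Validate a peptide observation table
#'
#' Checks every row against the observation contract: non-empty uppercase
#' amino-acid sequence, non-negative abundance and quality, replicate
#' indices within the design, known group/condition/subject labels when a
#' design is supplied, and modifications compatible with the sequence.
#' Validation is total: each row is either accepted or contributes at
#' least one located diagnostic; no row is silently dropped.
#'
#' @param obs A tibble/data.frame with the canonical observation columns.
#' @param design Optional `study_design` to validate design coordinates
#'   against.
#' @return A list with `valid` (the accepted rows, canonical column order
#'   and types) and `errors` (tibble of `row`, `message`).
#' @export
validate_observations <- function(obs, design = NULL) {
  missing_cols <- setdiff(OBS_COLUMNS, names(obs))
  if (length(missing_cols) > 0) {
    abort(sprintf(
      "observation table lacks mandatory column(s): %s",
      paste(missing_cols, collapse = ", ")
    ))
  }
  obs <- tibble::as_tibble(obs)[OBS_COLUMNS]
  obs$sequence <- toupper(as.character(obs$sequence))
  obs$modifications <- dplyr::coalesce(as.character(obs$modifications), "")
  obs$is_decoy <- as.logical(obs$is_decoy)

  n_cult <- if (is.null(design)) 3L else design$n_culture_reps
  n_tech <- if (is.null(design)) 2L else design$n_tech_reps
  subj <- if (is.null(design)) NULL else design_subjects(design)

  errs <- list()
  bad <- rep(FALSE, nrow(obs))
  note <- function(rows, msg) {
    if (length(rows) > 0) {
      bad[rows] <<- TRUE
      errs[[length(errs) + 1]] <<- tibble::tibble(row = rows, message = msg)
    }
  }

  seq_ok <- nzchar(obs$sequence) &
    !grepl(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")), obs$sequence)
  note(which(!seq_ok), "sequence empty or contains non-amino-acid letters")
  note(which(!is.na(obs$abundance) & obs$abundance < 0), "abundance < 0")
  note(which(!is.na(obs$quality) & obs$quality < 0), "quality < 0")
  note(
    which(is.na(obs$culture_rep) | obs$culture_rep < 1 | obs$culture_rep > n_cult),
    sprintf("culture_rep outside 1..%d", n_cult)
  )
  note(
    which(is.na(obs$tech_rep) | obs$tech_rep < 1 | obs$tech_rep > n_tech),
    sprintf("tech_rep outside 1..%d", n_tech)
  )
  if (!is.null(design)) {
    known <- paste(obs$subject_id, obs$group) %in% paste(subj$subject_id, subj$group)
    note(which(!known & !obs$is_decoy), "subject_id/group pair not in study design")
    note(
      which(!obs$condition %in% design$conditions),
      sprintf("condition not one of: %s", paste(design$conditions, collapse = ", "))
    )
  }
  for (i in which(seq_ok & nzchar(obs$modifications))) {
    mods <- tryCatch(parse_modifications(obs$modifications[i]),
      error = function(e) conditionMessage(e)
    )
    probs <- if (is.character(mods)) mods else check_modifications(obs$sequence[i], mods)
    if (length(probs) > 0) note(rep(i, length(probs)), probs)
  }

  errors <- if (length(errs) == 0) {
    tibble::tibble(row = integer(), message = character())
  } else {
    dplyr::arrange(dplyr::bind_rows(errs), .data$row)
  }
  list(valid = obs[!bad, , drop = FALSE], errors = errors)
}

#' Read a peptide observation table
#'
#' Reads the canonical long-format TSV (one identified peptide feature per
#' technical injection per row) or a foreign export whose column names are
#' supplied through `dialect`, validates every row, and returns accepted
#' rows plus a line-numbered report of rejected ones.
#'
#' @param path Path to a TSV/CSV file with a header row.
#' @param dialect Optional named character vector mapping canonical column
#'   names to the file's column names, e.g.
#'   `c(sequence = "Peptide", abundance = "Area")`. Canonical columns
#'   absent from the mapping are read under their canonical names.
#'   Columns with no counterpart in a foreign export may be defaulted:
#'   `modifications` to `""` and `is_decoy` to `FALSE`.
#' @param design Optional `study_design` for coordinate validation.
#' @param delim Field delimiter; `"\t"` (default) or `","`.
#' @param on_error `"collect"` (default) returns diagnostics alongside the
#'   valid rows; `"stop"` aborts if any row fails validation.
#' @return A tibble of valid observations with attribute `"errors"`
#'   holding the row-level diagnostic tibble.
#' @export
read_observations <- function(path, dialect = NULL, design = NULL,
                              delim = "\t", on_error = c("collect", "stop")) {
  on_error <- match.arg(on_error)
  if (!file.exists(path)) abort(sprintf("observation file not found: %s", path))
  raw <- readr::read_delim(
    path,
    delim = delim, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_character()),
    na = c("", "NA")
  )
  if (!is.null(dialect)) {
    for (canon in names(dialect)) {
      foreign <- dialect[[canon]]
      if (!foreign %in% names(raw)) {
        abort(sprintf("dialect maps '%s' to missing column '%s'", canon, foreign))
      }
      names(raw)[names(raw) == foreign] <- canon
    }
  }
  if (!"modifications" %in% names(raw)) raw$modifications <- ""
  if (!"is_decoy" %in% names(raw)) raw$is_decoy <- "FALSE"
  missing_cols <- setdiff(OBS_COLUMNS, names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf(
      "missing mandatory column(s): %s", paste(missing_cols, collapse = ", ")
    ))
  }
  raw <- raw[OBS_COLUMNS]

  # convert numerics ourselves so unparseable cells become row-level errors
  conv_errs <- list()
  num_field <- function(x, nm, to_int = FALSE) {
    out <- suppressWarnings(if (to_int) as.integer(x) else as.numeric(x))
    bad <- which(!is.na(x) & is.na(out))
    if (length(bad) > 0) {
      conv_errs[[length(conv_errs) + 1]] <<- tibble::tibble(
        row = bad, message = sprintf("unparseable %s: '%s'", nm, x[bad])
      )
    }
    out
  }
  raw$abundance <- num_field(raw$abundance, "abundance")
  raw$quality <- num_field(raw$quality, "quality")
  raw$rt_min <- num_field(raw$rt_min, "rt_min")
  raw$mz <- num_field(raw$mz, "mz")
  raw$culture_rep <- num_field(raw$culture_rep, "culture_rep", to_int = TRUE)
  raw$tech_rep <- num_field(raw$tech_rep, "tech_rep", to_int = TRUE)
  raw$is_decoy <- toupper(trimws(raw$is_decoy)) %in% c("TRUE", "T", "1")

  conv_bad <- sort(unique(unlist(lapply(conv_errs, `[[`, "row"))))
  keep <- setdiff(seq_len(nrow(raw)), conv_bad)
  res <- validate_observations(raw[keep, , drop = FALSE], design = design)
  res_errors <- res$errors
  res_errors$row <- keep[res_errors$row]  # report original data-row numbers
  errors <- dplyr::bind_rows(dplyr::bind_rows(conv_errs), res_errors)
  if (nrow(errors) > 0) errors <- dplyr::arrange(errors, .data$row)
  valid <- res$valid
  if (on_error == "stop" && nrow(errors) > 0) {
    abort(sprintf(
      "%d observation row(s) failed validation; first: row %d: %s",
      nrow(errors), errors$row[1], errors$message[1]
    ))
  }
  attr(valid, "errors") <- errors
  valid
}

#' Write a peptide observation table
#'
#' Writes the canonical tab-separated observation format (UTF-8, header
#' row). Missing abundances are written as `NA`, never as 0.
#'
#' @param obs Observation tibble with the canonical columns.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(obs, path) {
  missing_cols <- setdiff(OBS_COLUMNS, names(obs))
  if (length(missing_cols) > 0) {
    abort(sprintf("cannot write, missing: %s", paste(missing_cols, collapse = ", ")))
  }
  readr::write_tsv(obs[OBS_COLUMNS], path, progress = FALSE)
  invisible(path)
}
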