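#' Normalise a modified peptide to its genomically encoded backbone
#'
#' Identification engines report peptides with post-translational
#' modifications; mapping to the precursor must use the encoded residues.
#' The supported modifications are all mass-only with respect to the
#' letter sequence: methionine oxidation, N-terminal acetylation and
#' C-terminal amidation leave every residue letter unchanged, and
#' pyro-glutamate forms from an N-terminal Q or E, so the reported letter
#' is already the encoded one. The function therefore validates the
#' modification list against the sequence and returns the backbone
#' unchanged; incompatible modifications (e.g. oxidation on a non-M
#' residue) are an error.
#'
#' @param sequence Uppercase peptide amino-acid string.
#' @param modifications Modification string (see [parse_modifications()])
#'   or a tibble with columns `position`, `name`.
#' @return The backbone string used for substring search.
#' @examples
#' normalize_for_matching("QLEK", "N-term:pyro-glu")
#' @export
normalize_for_matching <- function(sequence, modifications = "") {
  sequence <- toupper(sequence)
  mods <- if (is.character(modifications)) {
    parse_modifications(modifications)
  } else {
    tibble::as_tibble(modifications)
  }
  probs <- check_modifications(sequence, mods)
  if (length(probs) > 0) {
    abort(sprintf("invalid modification for '%s': %s", sequence, probs[1]))
  }
  sequence
}

# All start positions of `pattern` in `subject`, overlapping occurrences
# included (a lookahead makes each match zero-width).
substring_starts <- function(pattern, subject) {
  esc <- gsub("([^A-Za-z0-9])", "\\\\\\1", pattern)
  m <- gregexpr(paste0("(?=", esc, ")"), subject, perl = TRUE)[[1]]
  if (m[1] == -1L) integer() else as.integer(m)
}

#' Map a peptide backbone onto precursor coordinates
#'
#' Exhaustive substring search of the backbone across every precursor.
#' All occurrences are recorded; the primary site is the lexicographically
#' smallest `(symbol, start)` pair. Coordinates are 1-based inclusive
#' residue numbers over the full precursor sequence (signal peptide
#' included), so `end - start + 1 == nchar(backbone)`. Isoleucine and
#' leucine are distinct letters. A peptide hitting more than one site
#' (within or across precursors) is flagged `ambiguous`.
#'
#' @param backbone Peptide backbone string (see [normalize_for_matching()]).
#' @param precursors Precursor tibble from [read_precursors()].
#' @return One-row tibble: `sequence`, `precursor_symbol`, `start`, `end`,
#'   `ambiguous`, `n_sites`, and list-column `all_sites` (tibble of
#'   `precursor_symbol`, `start`, `end`).
#' @export
map_peptide <- function(backbone, precursors) {
  if (nrow(precursors) == 0) abort("precursor set is empty")
  backbone <- toupper(backbone)
  len <- nchar(backbone)
  sites <- purrr::map_dfr(seq_len(nrow(precursors)), function(i) {
    starts <- substring_starts(backbone, precursors$sequence[i])
    if (length(starts) == 0) return(NULL)
    tibble::tibble(
      precursor_symbol = precursors$symbol[i],
      start = starts, end = starts + len - 1L
    )
  })
  if (nrow(sites) == 0) {
    abort(sprintf("peptide maps to no precursor: %s", backbone),
      class = "neuropepsig_no_match"
    )
  }
  sites <- dplyr::arrange(sites, .data$precursor_symbol, .data$start)
  tibble::tibble(
    sequence = backbone,
    precursor_symbol = sites$precursor_symbol[1],
    start = sites$start[1],
    end = sites$end[1],
    ambiguous = nrow(sites) > 1,
    n_sites = nrow(sites),
    all_sites = list(sites)
  )
}

#' Map every distinct peptide in an observation table
#'
#' Validates modifications, normalises to backbones, and maps each
#' distinct backbone with [map_peptide()]. Peptides matching no precursor
#' (decoys, contaminants) are reported rather than raised.
#'
#' @param obs Observation tibble.
#' @param precursors Precursor tibble.
#' @return Mapping tibble (one row per distinct mappable backbone) with
#'   attribute `"unmapped"`: character vector of backbones with no site.
#' @export
map_peptides <- function(obs, precursors) {
  keys <- dplyr::distinct(obs, .data$sequence, .data$modifications)
  backbones <- unique(vapply(
    seq_len(nrow(keys)),
    function(i) normalize_for_matching(keys$sequence[i], keys$modifications[i]),
    ""
  ))
  unmapped <- character()
  rows <- purrr::map(backbones, function(b) {
    tryCatch(map_peptide(b, precursors), neuropepsig_no_match = function(e) {
      unmapped <<- c(unmapped, b)
      NULL
    })
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(
      sequence = character(), precursor_symbol = character(),
      start = integer(), end = integer(), ambiguous = logical(),
      n_sites = integer(), all_sites = list()
    )
  }
  attr(out, "unmapped") <- unmapped
  out
}

#' Per-residue coverage of a precursor by mapped peptides
#'
#' Builds the annotation track behind peptide-map figures: for every
#' residue of the precursor, which mapped peptides cover it and with
#' which differential label (e.g. SZ-only / HC-only / shared).
#'
#' @param mapped Mapping tibble; every row must map to `precursor`.
#' @param precursor One-row precursor tibble (or list) with `symbol` and
#'   `sequence`.
#' @param labels Optional named character vector: peptide key
#'   (`"start-end"`) -> label. Unlabelled peptides get `NA`.
#' @return Tibble with one row per residue: `position`, `residue`,
#'   `n_peptides`, list-column `peptides` (covering `"start-end"` keys),
#'   list-column `labels`.
#' @export
coverage_map <- function(mapped, precursor, labels = NULL) {
  sym <- precursor$symbol[[1]]
  seq <- precursor$sequence[[1]]
  if (nrow(mapped) > 0 && !all(mapped$precursor_symbol == sym)) {
    abort(sprintf("coverage_map: peptide mapped to a precursor other than %s", sym))
  }
  n <- nchar(seq)
  if (nrow(mapped) > 0 && any(mapped$end > n)) {
    abort("mapped peptide extends beyond precursor sequence")
  }
  keys <- if (nrow(mapped) > 0) paste0(mapped$start, "-", mapped$end) else character()
  covering <- vector("list", n)
  for (i in seq_len(nrow(mapped))) {
    for (p in seq(mapped$start[i], mapped$end[i])) {
      covering[[p]] <- c(covering[[p]], keys[i])
    }
  }
  tibble::tibble(
    position = seq_len(n),
    residue = strsplit(seq, "")[[1]],
    n_peptides = lengths(covering),
    peptides = lapply(covering, function(k) k %||% character()),
    labels = lapply(covering, function(k) {
      if (is.null(k)) character() else unname(labels[k])
    })
  )
}

#' Render a coverage map as text
#'
#' Compact fixed-width rendering of a [coverage_map()] track: one line per
#' peptide interval, grouped by label, under a residue ruler.
#'
#' @param mapped Mapping tibble for one precursor.
#' @param precursor One-row precursor tibble.
#' @param labels Optional named labels as in [coverage_map()].
#' @param width Characters per ruler line.
#' @return Character vector of lines, invisibly; also printed.
#' @export
render_coverage <- function(mapped, precursor, labels = NULL, width = 80L) {
  sym <- precursor$symbol[[1]]
  n <- nchar(precursor$sequence[[1]])
  lines <- sprintf("%s (%d aa)", sym, n)
  if (nrow(mapped) > 0) {
    keys <- paste0(mapped$start, "-", mapped$end)
    lab <- if (is.null(labels)) rep("", length(keys)) else dplyr::coalesce(unname(labels[keys]), "")
    ord <- order(lab, mapped$start, mapped$end)
    for (i in ord) {
      bar_start <- max(1L, round(mapped$start[i] / n * width))
      bar_len <- max(1L, round((mapped$end[i] - mapped$start[i] + 1L) / n * width))
      bar <- paste0(
        strrep(" ", bar_start - 1L),
        strrep("=", min(bar_len, width - bar_start + 1L))
      )
      lines <- c(lines, sprintf("%-74s %9s %s", bar, keys[i], lab[i]))
    }
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
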