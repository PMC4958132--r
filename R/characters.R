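#' The seven religiosity characters
#'
#' Canonical names, in matrix order, of the binary characters describing
#' hunter-gatherer religiosity: animism, belief in an afterlife, shamanism,
#' ancestor worship, active ancestor worship, high gods, and active high
#' gods. The two "active" characters are derived from 4-state codings (see
#' [derive_binary_traits()]).
#'
#' @export
study_characters <- c("animism", "afterlife", "shamanism",
                      "ancestor_worship", "active_ancestor_worship",
                      "high_gods", "active_high_gods")

#' Derive nested binary characters from 4-state codings
#'
#' Ancestor worship and high gods are coded on a 4-point scale in the
#' cross-cultural databases: (1) absent; (2) present but inactive in human
#' affairs; (3) active but not influenced (ancestor spirits) / not supporting
#' morality (high gods); (4) active and influenced / morally punishing. Each
#' such column is recoded into two nested binary characters: *present*
#' (state >= 2) and *active* (state >= 3), so that active implies present for
#' every taxon.
#'
#' @param mat A character-matrix tibble (`taxon` column plus trait columns)
#'   whose `cols` columns hold states in `1:4` (or `NA`).
#' @param cols Names of the 4-state columns to recode. Each column `x` is
#'   replaced by binary `x` and `active_x`.
#' @return The recoded tibble; untouched columns are preserved.
#' @examples
#' m <- tibble::tibble(taxon = c("a", "b", "c"), ancestor_worship = c(1, 2, 3))
#' derive_binary_traits(m, "ancestor_worship")
#' @export
derive_binary_traits <- function(mat,
                                 cols = c("ancestor_worship", "high_gods")) {
  mat <- as_char_tibble(mat)
  for (cl in cols) {
    if (!cl %in% names(mat)) abort(sprintf("Column `%s` not found.", cl))
    x <- mat[[cl]]
    bad <- !is.na(x) & !(x %in% 1:4)
    if (any(bad)) {
      abort(sprintf("Column `%s` has states outside 1..4 (taxa: %s).",
                    cl, paste(mat$taxon[bad], collapse = ", ")))
    }
    present <- ifelse(is.na(x), NA_integer_, as.integer(x >= 2))
    active <- ifelse(is.na(x), NA_integer_, as.integer(x >= 3))
    mat[[cl]] <- present
    mat[[paste0("active_", cl)]] <- active
  }
  # keep the canonical study order where applicable
  ord <- intersect(c("taxon", study_characters), names(mat))
  dplyr::relocate(mat, dplyr::all_of(ord))
}

#' Trait prevalences
#'
#' Percentage of scored societies in which each binary trait is present.
#' Missing (`NA`) cells are excluded from the denominator, and a designated
#' outgroup row (by default the one recorded by [attach_outgroup()]) is
#' excluded entirely.
#'
#' @param mat A character-matrix tibble.
#' @param traits Traits to summarise (default: all trait columns).
#' @param outgroup Optional taxon label to exclude.
#' @return A tibble with columns `trait`, `n_present`, `n_scored`,
#'   `prevalence` (exact percent) and `prevalence_pct` (rounded half-up to a
#'   whole percent, the convention used when quoting prevalences in text).
#' @export
trait_prevalence <- function(mat, traits = NULL,
                             outgroup = attr(mat, "outgroup")) {
  mat <- as_char_tibble(mat)
  if (!is.null(outgroup)) {
    mat <- dplyr::filter(mat, .data$taxon != !!outgroup)
  }
  traits <- traits %||% trait_columns(mat)
  unknown <- setdiff(traits, names(mat))
  if (length(unknown)) {
    abort(paste0("Unknown character(s): ", paste(unknown, collapse = ", ")))
  }
  out <- purrr::map_dfr(traits, function(tr) {
    x <- mat[[tr]]
    bad <- !is.na(x) & !(x %in% 0:1)
    if (any(bad)) abort(sprintf("Character `%s` is not binary.", tr))
    n_scored <- sum(!is.na(x))
    n_present <- sum(x == 1, na.rm = TRUE)
    if (n_scored == 0) {
      warn(sprintf("Character `%s` has no scored taxa; prevalence is NaN.", tr))
    }
    tibble::tibble(trait = tr, n_present = n_present, n_scored = n_scored,
                   prevalence = 100 * n_present / n_scored)
  })
  dplyr::mutate(out, prevalence_pct = round_half_up(.data$prevalence))
}

#' Attach an all-absent hypothetical outgroup
#'
#' Adds a row in which every character is scored 0 (absent), the
#' plesiomorphic state, to root parsimony and likelihood reconstructions.
#' Calling it twice with the same label is an error.
#'
#' @param mat A character-matrix tibble.
#' @param label Outgroup taxon label.
#' @return The matrix with the outgroup row appended and an `outgroup`
#'   attribute recording the label.
#' @export
attach_outgroup <- function(mat, label = "Outgroup") {
  mat <- as_char_tibble(mat)
  if (label %in% mat$taxon) {
    abort(sprintf("Taxon `%s` already present; outgroup not attached twice.",
                  label))
  }
  row <- tibble::tibble(taxon = label)
  for (tr in trait_columns(mat)) row[[tr]] <- 0L
  out <- dplyr::bind_rows(mat, row)
  attr(out, "outgroup") <- label
  out
}

#' Read / write character matrices as CSV
#'
#' The CSV has a `taxon` column followed by one column per character; an
#' optional JSON sidecar (`<path>.meta.json`) documents state semantics.
#'
#' @param file Path to a CSV file.
#' @return A character-matrix tibble; if a sidecar exists its contents are
#'   attached as the `meta` attribute.
#' @export
read_char_csv <- function(file) {
  mat <- as_char_tibble(utils::read.csv(file, stringsAsFactors = FALSE,
                                        check.names = FALSE))
  sidecar <- paste0(file, ".meta.json")
  if (file.exists(sidecar)) {
    attr(mat, "meta") <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  }
  mat
}

#' @param mat A character-matrix tibble.
#' @param meta Optional named list describing each character's states,
#'   written to the JSON sidecar.
#' @rdname read_char_csv
#' @export
write_char_csv <- function(mat, file, meta = NULL) {
  utils::write.csv(as_char_tibble(mat), file, row.names = FALSE, quote = FALSE)
  if (!is.null(meta)) {
    jsonlite::write_json(meta, paste0(file, ".meta.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(file)
}

#' Read / write character matrices as a NEXUS DATA block
#'
#' @param file Path to a NEXUS file.
#' @param missing_char Symbol used for missing data.
#' @return `read_char_nexus()` returns a character-matrix tibble with
#'   integer states (`NA` for missing).
#' @export
read_char_nexus <- function(file, missing_char = "?") {
  raw <- ape::read.nexus.data(file)
  taxa <- names(raw)
  nchar <- length(raw[[1]])
  X <- matrix(NA_integer_, length(taxa), nchar)
  for (i in seq_along(taxa)) {
    v <- unlist(raw[[i]])
    v[v == missing_char] <- NA
    X[i, ] <- suppressWarnings(as.integer(v))
  }
  out <- tibble::as_tibble(as.data.frame(X))
  names(out) <- paste0("char", seq_len(nchar))
  dplyr::bind_cols(tibble::tibble(taxon = taxa), out)
}

#' @rdname read_char_nexus
#' @export
write_char_nexus <- function(mat, file, missing_char = "?") {
  mat <- as_char_tibble(mat)
  traits <- trait_columns(mat)
  rows <- purrr::map_chr(seq_len(nrow(mat)), function(i) {
    states <- purrr::map_chr(traits, function(tr) {
      v <- mat[[tr]][i]
      if (is.na(v)) missing_char else as.character(v)
    })
    sprintf("    %s  %s", gsub("\\s", "_", mat$taxon[i]),
            paste(states, collapse = ""))
  })
  symbols <- sort(unique(stats::na.omit(unlist(mat[traits]))))
  lines <- c(
    "#NEXUS", "BEGIN DATA;",
    sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", nrow(mat), length(traits)),
    sprintf("  FORMAT DATATYPE=STANDARD MISSING=%s SYMBOLS=\"%s\";",
            missing_char, paste(symbols, collapse = "")),
    "  MATRIX", rows, "  ;", "END;")
  writeLines(lines, file)
  invisible(file)
}
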