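#' Parse a SCOP concise classification string (sccs)
#'
#' An sccs token such as `"a.38.1.2"` encodes the Class / Fold / Superfamily /
#' Family path of a protein domain: a single-letter class followed by one to
#' three positive-integer components. Depth-2 and depth-3 tokens (fold- and
#' superfamily-level prefixes, as used in report tables) are accepted; domain
#' records themselves require depth 4.
#'
#' @param text A single sccs token, e.g. `"a.38.1.2"` or `"e.1.1"`.
#' @return An object of class `ClassificationPath`: a list with `class_id`,
#'   `fold_id`, `superfamily_id`, `family_id` (NA when absent) and `depth`.
#' @examples
#' parse_sccs("a.38.1")    # superfamily-level prefix, depth 3
#' parse_sccs("a.38.1.2")  # full domain classification, depth 4
#' @export
parse_sccs <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    stopf("sccs must be a single character string")
  }
  parts <- strsplit(text, ".", fixed = TRUE)[[1]]
  n <- length(parts)
  if (n < 2L || n > 4L) {
    stopf("malformed sccs '%s': expected 2-4 dot-separated components, got %d",
          text, n)
  }
  if (!grepl("^[A-Za-z]$", parts[1])) {
    stopf("malformed sccs '%s': class component '%s' is not a single letter",
          text, parts[1])
  }
  for (k in 2:n) {
    if (!grepl("^[0-9]+$", parts[k]) || as.numeric(parts[k]) < 1) {
      stopf("malformed sccs '%s': component '%s' is not a positive integer",
            text, parts[k])
    }
  }
  path <- list(
    class_id       = parts[1],
    fold_id        = paste(parts[1:2], collapse = "."),
    superfamily_id = if (n >= 3L) paste(parts[1:3], collapse = ".") else NA_character_,
    family_id      = if (n == 4L) paste(parts[1:4], collapse = ".") else NA_character_,
    depth          = n
  )
  class(path) <- "ClassificationPath"
  path
}

#' Format a classification path back to its sccs token
#'
#' Inverse of [parse_sccs()]: returns the deepest populated id string.
#'
#' @param path A `ClassificationPath`.
#' @return A single sccs string.
#' @export
format_sccs <- function(path) {
  stopifnot(inherits(path, "ClassificationPath"))
  switch(as.character(path$depth),
    "2" = path$fold_id,
    "3" = path$superfamily_id,
    "4" = path$family_id,
    stopf("invalid depth %s", path$depth))
}

#' @export
print.ClassificationPath <- function(x, ...) {
  cat(sprintf("<ClassificationPath depth %d> %s\n", x$depth, format_sccs(x)))
  invisible(x)
}

# Vectorised sccs split used by the readers; returns a data.frame with one row
# per token and an `ok` column instead of raising on malformed rows.
split_sccs_vec <- function(sccs) {
  parts <- strsplit(sccs, ".", fixed = TRUE)
  n <- lengths(parts)
  first <- vapply(parts, function(p) if (length(p)) p[1] else "", "")
  rest_ok <- vapply(parts, function(p) {
    length(p) < 2L || all(grepl("^[0-9]+$", p[-1]))
  }, TRUE)
  ok <- n >= 2L & n <= 4L & grepl("^[A-Za-z]$", first) & rest_ok
  comp <- function(k) {
    vapply(seq_along(parts), function(i) {
      if (ok[i] && n[i] >= k) paste(parts[[i]][1:k], collapse = ".") else NA_character_
    }, "")
  }
  data.frame(
    class_id = ifelse(ok, first, NA_character_),
    fold_id = comp(2L), superfamily_id = comp(3L), family_id = comp(4L),
    depth = ifelse(ok, n, NA_integer_),
    ok = ok, stringsAsFactors = FALSE
  )
}

valid_sequence <- function(seq) {
  nzchar(seq) & grepl("^[ACDEFGHIKLMNPQRSTVWYXBZU]+$", seq)
}

#' Construct a classified domain database
#'
#' A `DomainDatabase` is a data frame with one row per protein domain and
#' columns `domain_id`, `sccs`, `class_id`, `fold_id`, `superfamily_id`,
#' `family_id`, `sequence`, `span_count` and `description`. Every record must
#' carry a depth-4 classification and a non-empty amino-acid sequence over the
#' 20 standard letters plus X/B/Z/U.
#'
#' @param domain_id,sccs,sequence Character vectors of equal length.
#' @param span_count Integer vector (default 1): number of discontinuous
#'   structural spans the sequence represents.
#' @param description Free-text vector (default "").
#' @param identity_threshold_label Optional fraction in (0, 1]: the maximum
#'   pairwise sequence identity of the (pre-filtered) database, kept as
#'   provenance metadata.
#' @return A `DomainDatabase` data frame.
#' @export
domain_database <- function(domain_id, sccs, sequence,
                            span_count = 1L, description = "",
                            identity_threshold_label = NULL) {
  n <- length(domain_id)
  stopifnot(length(sccs) == n, length(sequence) == n)
  span_count <- rep_len(as.integer(span_count), n)
  description <- rep_len(as.character(description), n)
  if (anyDuplicated(domain_id)) {
    dup <- unique(domain_id[duplicated(domain_id)])
    stopf("duplicate domain ids: %s", paste(dup, collapse = ", "))
  }
  cls <- split_sccs_vec(sccs)
  bad <- !cls$ok | is.na(cls$family_id)
  if (any(bad)) {
    stopf("records without a valid depth-4 sccs: %s",
          paste(domain_id[bad], collapse = ", "))
  }
  sequence <- toupper(sequence)
  if (any(!valid_sequence(sequence))) {
    stopf("invalid amino-acid sequences for: %s",
          paste(domain_id[!valid_sequence(sequence)], collapse = ", "))
  }
  db <- data.frame(
    domain_id = as.character(domain_id), sccs = as.character(sccs),
    class_id = cls$class_id, fold_id = cls$fold_id,
    superfamily_id = cls$superfamily_id, family_id = cls$family_id,
    sequence = sequence, span_count = span_count, description = description,
    stringsAsFactors = FALSE
  )
  rownames(db) <- NULL
  if (!is.null(identity_threshold_label)) {
    if (identity_threshold_label <= 0 || identity_threshold_label > 1) {
      stopf("identity_threshold_label must lie in (0, 1]")
    }
    attr(db, "identity_threshold_label") <- identity_threshold_label
  }
  class(db) <- c("DomainDatabase", "data.frame")
  db
}

#' Read an Astral-style FASTA file into a domain database
#'
#' Headers follow the de-facto Astral dialect: the domain id is the first
#' whitespace token, the depth-4 sccs the second, and the first parenthesised
#' field describes the structural region(s); comma-separated regions mark
#' domains assembled from more than one continuous span. Records with a
#' missing or malformed sccs are dropped and collected into a report attached
#' as `attr(, "skipped")` rather than aborting the read.
#'
#' @param path Path to a FASTA file.
#' @param identity_threshold_label Optional provenance label, see
#'   [domain_database()].
#' @return A `DomainDatabase`.
#' @export
read_astral_fasta <- function(path, identity_threshold_label = NULL) {
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0L) stopf("no FASTA records in '%s'", path)
  headers <- names(seqs)
  tokens <- strsplit(trimws(headers), "\\s+")
  id <- vapply(tokens, function(t) if (length(t) >= 1L) t[1] else "", "")
  sccs <- vapply(tokens, function(t) if (length(t) >= 2L) t[2] else "", "")
  region <- vapply(headers, function(h) {
    m <- regmatches(h, regexpr("\\(([^)]*)\\)", h))
    if (length(m)) substr(m, 2L, nchar(m) - 1L) else ""
  }, "", USE.NAMES = FALSE)
  span_count <- ifelse(nzchar(region),
                       lengths(strsplit(region, ",", fixed = TRUE)), 1L)
  description <- vapply(headers, function(h) {
    trimws(sub("^\\S+\\s+\\S+\\s*(\\([^)]*\\))?\\s*", "", h))
  }, "", USE.NAMES = FALSE)

  cls <- split_sccs_vec(sccs)
  usable <- cls$ok & !is.na(cls$family_id) &
    valid_sequence(toupper(as.character(seqs)))
  if (anyDuplicated(id[usable])) {
    dup <- unique(id[usable][duplicated(id[usable])])
    stopf("duplicate domain ids in '%s': %s", path, paste(dup, collapse = ", "))
  }
  skipped <- data.frame(header = headers[!usable],
                        reason = "missing or malformed sccs token or sequence",
                        stringsAsFactors = FALSE)
  if (!any(usable)) stopf("no usable records in '%s'", path)
  db <- domain_database(
    domain_id = id[usable], sccs = sccs[usable],
    sequence = as.character(seqs)[usable],
    span_count = as.integer(span_count[usable]),
    description = description[usable],
    identity_threshold_label = identity_threshold_label
  )
  attr(db, "skipped") <- skipped
  db
}

#' Read a TSV annotation table into a domain database
#'
#' A plain-text alternative to FASTA for synthetic and test data: tab-separated
#' with a header row and at least the columns `domain_id`, `sccs`, `sequence`
#' (optionally `span_count`, `description`). Rows with a malformed or
#' non-depth-4 sccs are rejected and reported via `attr(, "skipped")`.
#'
#' @param path Path to the TSV file.
#' @param identity_threshold_label Optional provenance label.
#' @return A `DomainDatabase` (possibly empty, with a warning).
#' @export
read_annotation_table <- function(path, identity_threshold_label = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  required <- c("domain_id", "sccs", "sequence")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    stopf("annotation table '%s' lacks required column(s): %s",
          path, paste(missing_cols, collapse = ", "))
  }
  if (nrow(tab) == 0L) {
    warnf("annotation table '%s' has no data rows", path)
    db <- empty_domain_database(identity_threshold_label)
    attr(db, "skipped") <- data.frame(domain_id = character(),
                                      reason = character())
    return(db)
  }
  cls <- split_sccs_vec(tab$sccs)
  usable <- cls$ok & !is.na(cls$family_id) & valid_sequence(toupper(tab$sequence))
  skipped <- data.frame(domain_id = tab$domain_id[!usable],
                        reason = rep("malformed or non-depth-4 sccs or bad sequence",
                                     sum(!usable)),
                        stringsAsFactors = FALSE)
  if (nrow(skipped)) {
    warnf("%d row(s) rejected while reading '%s'", nrow(skipped), path)
  }
  if (!any(usable)) {
    db <- empty_domain_database(identity_threshold_label)
    attr(db, "skipped") <- skipped
    return(db)
  }
  db <- domain_database(
    domain_id = tab$domain_id[usable], sccs = tab$sccs[usable],
    sequence = tab$sequence[usable],
    span_count = if ("span_count" %in% names(tab))
      as.integer(tab$span_count[usable]) else 1L,
    description = if ("description" %in% names(tab))
      tab$description[usable] else "",
    identity_threshold_label = identity_threshold_label
  )
  attr(db, "skipped") <- skipped
  db
}

empty_domain_database <- function(identity_threshold_label = NULL) {
  db <- data.frame(domain_id = character(), sccs = character(),
                   class_id = character(), fold_id = character(),
                   superfamily_id = character(), family_id = character(),
                   sequence = character(), span_count = integer(),
                   description = character(), stringsAsFactors = FALSE)
  if (!is.null(identity_threshold_label)) {
    attr(db, "identity_threshold_label") <- identity_threshold_label
  }
  class(db) <- c("DomainDatabase", "data.frame")
  db
}

#' Write a domain database as a TSV annotation table
#'
#' Round-trips with [read_annotation_table()].
#'
#' @param db A `DomainDatabase`.
#' @param path Output path.
#' @export
write_annotation_table <- function(db, path) {
  stopifnot(inherits(db, "DomainDatabase"))
  out <- db[, c("domain_id", "sccs", "sequence", "span_count", "description")]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Apply preprocessing filters to a domain database
#'
#' Two filters mirror the minimal curation applied before building retrieval
#' tasks: removal of whole Folds known to blur homology boundaries (for
#' example Rossmann-like folds and four- to eight-bladed beta-propellers;
#' supplied as an explicit id list because the choice is a curation decision,
#' not an algorithm), and removal of sequences stitched together from more
#' than one continuous structural span.
#'
#' @param db A `DomainDatabase`.
#' @param excluded_fold_ids Character vector of fold ids (e.g. `"c.2"`) to
#'   remove wholesale. Default: none.
#' @param require_single_span If `TRUE`, drop records with `span_count > 1`.
#' @return The filtered `DomainDatabase`, with a `FilterReport` data frame
#'   (`rule`, `removed`) in `attr(, "filter_report")`. The input is not
#'   modified.
#' @export
apply_preprocessing_filters <- function(db, excluded_fold_ids = character(),
                                        require_single_span = FALSE) {
  stopifnot(inherits(db, "DomainDatabase"))
  by_fold <- db$fold_id %in% excluded_fold_ids
  by_span <- if (require_single_span) !by_fold & db$span_count > 1L
             else rep(FALSE, nrow(db))
  keep <- !(by_fold | by_span)
  report <- data.frame(
    rule = c("excluded_fold", "multi_span"),
    removed = c(sum(by_fold), sum(by_span)),
    stringsAsFactors = FALSE
  )
  out <- db[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "identity_threshold_label") <- attr(db, "identity_threshold_label")
  class(out) <- c("DomainDatabase", "data.frame")
  if (nrow(out) == 0L) warnf("all records removed by preprocessing filters")
  attr(out, "filter_report") <- report
  out
}

# Percent identity of two sequences under optimal global alignment with
# match 1, mismatch 0, linear gap -1; identity = identical positions divided
# by alignment length (gap columns included).
pairwise_identity <- function(a, b) {
  alphabet <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q",
                "R","S","T","V","W","Y","X","B","Z","U")
  subm <- diag(1, length(alphabet))
  dimnames(subm) <- list(alphabet, alphabet)
  aln <- Biostrings::pairwiseAlignment(
    a, b, type = "global", substitutionMatrix = subm,
    gapOpening = 0, gapExtension = 1
  )
  Biostrings::nmatch(aln) / nchar(as.character(Biostrings::alignedPattern(aln)))
}

#' Greedy sequence-identity filter (toy scale)
#'
#' A desk-scale stand-in for CD-HIT style redundancy removal, for synthetic
#' and test databases only: sequences are visited longest-first (ties broken
#' by ascending `domain_id`) and a sequence is retained iff its global percent
#' identity to every already-retained sequence is at most `th`. Identity is
#' identical positions over alignment length under an optimal global alignment
#' scoring match 1, mismatch 0, linear gap -1. Deterministic for a given
#' input.
#'
#' @param db A `DomainDatabase`.
#' @param th Identity threshold, a fraction in (0, 1]; retained pairs never
#'   exceed it.
#' @param max_len Guard: refuse databases with any sequence longer than this
#'   (exact all-pairs alignment is quadratic). Default 2000.
#' @return The filtered `DomainDatabase` with `identity_threshold_label = th`.
#' @export
greedy_identity_filter <- function(db, th, max_len = 2000L) {
  stopifnot(inherits(db, "DomainDatabase"))
  if (!is.numeric(th) || length(th) != 1L || th <= 0 || th > 1) {
    stopf("identity threshold must lie in (0, 1]")
  }
  if (nrow(db) == 0L) return(db)
  if (any(nchar(db$sequence) > max_len)) {
    stopf("sequences longer than %d are not supported by the toy filter", max_len)
  }
  ord <- order(-nchar(db$sequence), db$domain_id)
  kept <- integer(0)
  for (i in ord) {
    clash <- FALSE
    for (j in kept) {
      if (pairwise_identity(db$sequence[i], db$sequence[j]) > th) {
        clash <- TRUE
        break
      }
    }
    if (!clash) kept <- c(kept, i)
  }
  out <- db[sort(kept), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "identity_threshold_label") <- th
  class(out) <- c("DomainDatabase", "data.frame")
  out
}
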