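#' Normalize gene/TF names for exact matching
#'
#' Names are compared after Unicode NFC normalization (when \pkg{stringi}
#' is available; bacterial gene symbols are ASCII in practice) and
#' lower-casing, so that `AraC`, `araC` and `ARAC` resolve to the same node.
#'
#' @param x character vector of names.
#' @return normalized character vector.
#' @export
normalize_gene_name <- function(x) {
  x <- enc2utf8(trimws(as.character(x)))
  if (requireNamespace("stringi", quietly = TRUE)) {
    x <- stringi::stri_trans_nfc(x)
  }
  tolower(x)
}

#' Default regulatory-effect dialect
#'
#' Maps effect tokens of a RegulonDB-style export to the signed regulatory
#' effect r: activator -> +1, repressor -> -1, unknown and dual -> 0.
#' Dual ("+-") regulators are deliberately treated like unknown ones: the
#' signed logic only admits r in \{-1, 0, +1\}, and mapping dual to 0 keeps
#' the bias bounded by the in-degree (b <= K_TF).
#'
#' @return named integer vector token -> r.
#' @export
default_effect_dialect <- function() {
  c("+" = 1L, "activator" = 1L, "activation" = 1L,
    "-" = -1L, "repressor" = -1L, "repression" = -1L,
    "+-" = 0L, "-+" = 0L, "dual" = 0L, "?" = 0L, "unknown" = 0L)
}

.known_target_kinds <- c("gene", "tf", "operon", "tu")

#' Parse a regulatory-interaction table
#'
#' Reads a tab-separated table with columns
#' `regulator  target  target_kind  effect` into one interaction record per
#' row (row order preserved). `target_kind` must be one of
#' gene / tf / operon / tu; effect tokens are translated through `dialect`.
#'
#' @param path file path of the TSV table (with header).
#' @param dialect named integer vector mapping effect tokens to r in
#'   \{-1, 0, 1\}; see [default_effect_dialect()].
#' @return data.frame with columns `regulator`, `target`, `target_kind`
#'   (character) and `effect` (integer).
#' @export
parse_interactions <- function(path, dialect = default_effect_dialect()) {
  stopifnot(file.exists(path))
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", quote = "",
                           check.names = FALSE, comment.char = "")
  required <- c("regulator", "target", "target_kind", "effect")
  if (!all(required %in% names(tab))) {
    stop("interaction table must declare columns: ",
         paste(required, collapse = ", "))
  }
  interaction_records(tab$regulator, tab$target, tab$target_kind, tab$effect,
                      dialect = dialect)
}

#' Build interaction records from vectors
#'
#' @param regulator,target,target_kind,effect parallel vectors; `effect` may
#'   be dialect tokens (character) or already-signed integers in \{-1,0,1\}.
#' @param dialect token map used when `effect` is character.
#' @return data.frame of interaction records.
#' @export
interaction_records <- function(regulator, target, target_kind, effect,
                                dialect = default_effect_dialect()) {
  regulator <- as.character(regulator)
  target <- as.character(target)
  target_kind <- tolower(trimws(as.character(target_kind)))
  if (any(!nzchar(trimws(regulator))) || any(!nzchar(trimws(target)))) {
    stop("regulator and target names must be non-empty")
  }
  bad_kind <- which(!target_kind %in% .known_target_kinds)
  if (length(bad_kind)) {
    stop("unknown target_kind '", target_kind[bad_kind[1]],
         "' at row ", bad_kind[1])
  }
  if (is.character(effect) || is.factor(effect)) {
    tok <- trimws(as.character(effect))
    r <- unname(dialect[tok])
    bad <- which(is.na(r))
    if (length(bad)) {
      stop("unknown effect token '", tok[bad[1]], "' at row ", bad[1])
    }
  } else {
    r <- as.integer(effect)
    if (any(is.na(r)) || any(!r %in% c(-1L, 0L, 1L))) {
      stop("numeric effects must be -1, 0 or +1")
    }
  }
  data.frame(regulator = regulator, target = target,
             target_kind = target_kind, effect = as.integer(r),
             stringsAsFactors = FALSE)
}

#' Read an operon/transcription-unit annotation table
#'
#' Expects TSV columns `unit_id  unit_kind  gene  position` (1-based
#' position within the unit, position 1 = promoter-proximal).
#'
#' @param path annotation TSV path.
#' @return data.frame with those four columns, positions integer.
#' @export
read_unit_annotation <- function(path) {
  stopifnot(file.exists(path))
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", quote = "",
                           check.names = FALSE, comment.char = "")
  required <- c("unit_id", "unit_kind", "gene", "position")
  if (!all(required %in% names(tab))) {
    stop("annotation table must declare columns: ",
         paste(required, collapse = ", "))
  }
  unit_annotation(tab$unit_id, tab$unit_kind, tab$gene,
                  as.integer(tab$position))
}

#' Build a unit annotation from vectors
#'
#' @param unit_id,unit_kind,gene,position parallel vectors; `unit_kind` in
#'   \{operon, tu\}; no duplicate gene within one unit.
#' @return validated annotation data.frame.
#' @export
unit_annotation <- function(unit_id, unit_kind, gene, position) {
  ann <- data.frame(unit_id = as.character(unit_id),
                    unit_kind = tolower(trimws(as.character(unit_kind))),
                    gene = as.character(gene),
                    position = as.integer(position),
                    stringsAsFactors = FALSE)
  if (any(!ann$unit_kind %in% c("operon", "tu"))) {
    stop("unit_kind must be 'operon' or 'tu'")
  }
  if (any(!nzchar(trimws(ann$gene)))) stop("unit member genes must be named")
  dup <- duplicated(ann[c("unit_id", "gene")])
  if (any(dup)) {
    stop("duplicate gene within unit: ", ann$unit_id[which(dup)[1]])
  }
  ann[order(ann$unit_id, ann$position), , drop = FALSE]
}
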