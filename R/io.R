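#' Read protein sequences from a FASTA file
#'
#' Each entry becomes one protein record.  The identifier is the header
#' token up to the first whitespace; the remainder of the header is kept as
#' the description.  Sequences are upper-cased; letters outside the 20
#' amino-acid alphabet plus `X` are kept but reported with a warning, since
#' search over permissive alphabets is preferable to silently dropping
#' residues.
#'
#' @param path path to a FASTA file.
#' @return a data.frame with columns `id` and `sequence`, one row per
#'   entry, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_("FASTA file not found: %s", path)
  aas <- Biostrings::readAAStringSet(path)
  if (length(aas) == 0L) {
    warning("empty FASTA file: ", path)
    return(data.frame(id = character(), sequence = character(),
                      stringsAsFactors = FALSE))
  }
  ids <- vapply(strsplit(names(aas), "[ \t]+"), `[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop_("duplicate id %s in %s", ids[duplicated(ids)][1], path)
  }
  seqs <- toupper(as.character(aas))
  if (any(!nzchar(seqs))) stop_("zero-length sequence in %s", path)
  odd <- grepl("[^ACDEFGHIKLMNPQRSTVWYX]", seqs)
  if (any(odd)) {
    warning("sequences with letters outside the 20+X amino-acid alphabet: ",
            paste(ids[odd], collapse = ", "))
  }
  data.frame(id = ids, sequence = unname(seqs), stringsAsFactors = FALSE)
}

#' Write protein records to a FASTA file
#'
#' @param records data.frame with columns `id` and `sequence`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  aas <- Biostrings::AAStringSet(setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(aas, path, width = 60L)
  invisible(path)
}

#' Read a Pfam family-to-clan mapping table
#'
#' Parses the first two columns of a `Pfam-A.clans.tsv`-style TSV: family
#' accession then clan accession.  Rows whose clan field is empty are
#' omitted from the map; such families fall back to acting as their own
#' clan at assignment time (see [assign_clans()]).
#'
#' @param path path to a TSV file.
#' @return a named character vector mapping family accession to clan
#'   accession.
#' @export
read_clan_map <- function(path) {
  if (!file.exists(path)) stop_("clan map file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(setNames(character(), character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 2L)
  if (length(bad)) stop_("malformed clan map row at line %d of %s", bad[1], path)
  fam <- vapply(fields, `[`, character(1), 1L)
  clan <- vapply(fields, `[`, character(1), 2L)
  keep <- nzchar(clan)
  setNames(clan[keep], fam[keep])
}

#' Read PfamScan-style domain annotations
#'
#' Accepts the whitespace-delimited tabular output of a Pfam domain scan:
#' comment lines start with `#`; the sequence identifier is in the first
#' column and the HMM accession in `acc_col`.  Version suffixes on
#' accessions (e.g. `PF00001.21`) are stripped so annotations join cleanly
#' with the clan map.  Hits are aggregated into one family set per protein.
#'
#' @param path path to the annotation table.
#' @param acc_col 1-based column index of the HMM accession (default 6,
#'   the PfamScan layout).
#' @return a named list mapping protein id to a character vector of family
#'   accessions (unique, sorted).  Proteins absent from the file are simply
#'   absent; callers treat them as having an empty family set.
#' @export
read_domain_annotations <- function(path, acc_col = 6L) {
  if (!file.exists(path)) stop_("annotation file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  if (length(lines) == 0L) return(structure(list(), names = character()))
  fields <- strsplit(trimws(lines), "\\s+")
  if (any(lengths(fields) < acc_col)) {
    stop_("annotation table is missing the hmm accession column (expected >= %d columns)",
          acc_col)
  }
  ids <- vapply(fields, `[`, character(1), 1L)
  acc <- sub("\\.\\d+$", "", vapply(fields, `[`, character(1), acc_col))
  split_acc <- split(acc, ids)
  ann <- lapply(split_acc, function(a) sort(unique(a)))
  ann[order(names(ann))]
}

#' Write domain annotations in PfamScan-like tabular form
#'
#' @param annotations named list of family-accession vectors (as returned
#'   by [read_domain_annotations()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_domain_annotations <- function(annotations, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# <seq id> <aln start> <aln end> <env start> <env end> <hmm acc>", con)
  for (id in names(annotations)) {
    for (a in annotations[[id]]) {
      writeLines(sprintf("%s 1 1 1 1 %s", id, a), con)
    }
  }
  invisible(path)
}

#' Read a TM-score label table
#'
#' @param path TSV with columns query_id, target_id, tm_score (no header).
#' @return data.frame with columns `query`, `target`, `tm_score`.
#' @export
read_labeled_pairs <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                   col.names = c("query", "target", "tm_score"))
  if (any(df$tm_score < 0 | df$tm_score > 1)) {
    stop_("tm_score outside [0,1] in %s", path)
  }
  df
}

#' Write a TM-score label table
#' @param pairs data.frame with columns `query`, `target`, `tm_score`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_labeled_pairs <- function(pairs, path) {
  write.table(pairs[, c("query", "target", "tm_score")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a fold-hierarchy label table
#'
#' The table assigns each protein a family, superfamily and fold in the
#' SCOP sense (class > fold > superfamily > family).  Hierarchy consistency
#' is validated on load: a family must determine its superfamily and a
#' superfamily its fold, otherwise the level-based true-positive
#' definitions used in evaluation would be ambiguous.
#'
#' @param path TSV with columns protein_id, family, superfamily, fold
#'   (no header).
#' @return data.frame with columns `id`, `family`, `superfamily`, `fold`.
#' @export
read_fold_labels <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                   col.names = c("id", "family", "superfamily", "fold"))
  validate_fold_labels(df)
  df
}

#' Validate fold-label hierarchy consistency
#'
#' @param labels data.frame with columns `id`, `family`, `superfamily`,
#'   `fold`.
#' @return `labels`, invisibly; errors if a family maps to more than one
#'   superfamily or a superfamily to more than one fold.
#' @export
validate_fold_labels <- function(labels) {
  stopifnot(all(c("id", "family", "superfamily", "fold") %in% names(labels)))
  if (anyDuplicated(labels$id)) {
    stop_("duplicate protein id in fold labels: %s",
          labels$id[duplicated(labels$id)][1])
  }
  fam_sf <- unique(labels[, c("family", "superfamily")])
  if (anyDuplicated(fam_sf$family)) {
    stop_("family %s maps to more than one superfamily",
          fam_sf$family[duplicated(fam_sf$family)][1])
  }
  sf_fold <- unique(labels[, c("superfamily", "fold")])
  if (anyDuplicated(sf_fold$superfamily)) {
    stop_("superfamily %s maps to more than one fold",
          sf_fold$superfamily[duplicated(sf_fold$superfamily)][1])
  }
  invisible(labels)
}

#' Write a fold-hierarchy label table
#' @param labels data.frame with columns `id`, `family`, `superfamily`, `fold`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fold_labels <- function(labels, path) {
  validate_fold_labels(labels)
  write.table(labels[, c("id", "family", "superfamily", "fold")], path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
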