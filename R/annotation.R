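#' RNA-class priority hierarchy
#'
#' The eight small RNA classes handled by the package, ordered from highest
#' to lowest annotation priority. When a sequence maps to references of
#' several classes, the candidate of the highest-ranking class wins.
#'
#' @return Character vector of the eight class names in priority order.
#' @export
rna_class_priority <- function() {
  c("miRNA", "tRNA", "rRNA", "YRNA", "snoRNA", "lncRNA", "snRNA", "piRNA")
}

#' Bin label for an rRNA- or Y RNA-derived fragment
#'
#' Fragments of long parental transcripts are subcategorized by the ~25-nt
#' bin of the parent that contains the fragment's first nucleotide. Bins are
#' 1-based and contiguous: bin k covers positions
#' `[bin_size*(k-1)+1, bin_size*k]`.
#'
#' @param parent_gene gene symbol of the parental transcript.
#' @param start_pos 1-based start position of the fragment on the parent.
#' @param bin_size bin width in nucleotides (default 25).
#' @return Character label `"<parent_gene>-bin<k>"` with `k = ceiling(start_pos / bin_size)`.
#' @examples
#' bin_label("RNY1", 1)    # "RNY1-bin1"
#' bin_label("RNY1", 26)   # "RNY1-bin2"
#' @export
bin_label <- function(parent_gene, start_pos, bin_size = 25) {
  if (bin_size < 1) stop("`bin_size` must be >= 1")
  start_pos <- as.numeric(start_pos)
  if (anyNA(start_pos) || any(start_pos < 1))
    stop("`start_pos` must be >= 1 (1-based coordinates)")
  k <- ceiling(start_pos / bin_size)
  paste0(parent_gene, "-bin", k)
}

# synthesize the label a single candidate would receive
candidate_label <- function(rna_class, parent_gene, start_pos,
                            bin_size = 25) {
  binned <- rna_class %in% c("rRNA", "YRNA")
  out <- as.character(parent_gene)
  if (any(binned)) {
    if (anyNA(start_pos[binned]))
      stop("rRNA/YRNA candidates require `start_pos`")
    out[binned] <- bin_label(parent_gene[binned], start_pos[binned], bin_size)
  }
  out
}

#' Resolve multi-class annotation candidates to a single label
#'
#' Applies the class priority
#' miRNA > tRNA > rRNA > Y RNA > snoRNA > lncRNA > snRNA > piRNA.
#' rRNA and Y RNA candidates receive positional bin labels
#' (see [bin_label()]); other classes are labelled by their gene/feature
#' name. Ties within the winning class are broken by the lexicographically
#' smallest label (C collation), making resolution order-independent.
#'
#' @param candidates data frame with columns `rna_class`, `parent_gene` and
#'   (required for rRNA/YRNA) `start_pos`.
#' @param bin_size bin width for rRNA/YRNA labels.
#' @return List with elements `label` and `rna_class`.
#' @export
resolve_assignment <- function(candidates, bin_size = 25) {
  if (is.null(candidates) || nrow(candidates) == 0)
    stop("candidate list is empty")
  cls <- as.character(candidates$rna_class)
  rank <- match(cls, rna_class_priority())
  if (anyNA(rank))
    stop("unknown RNA class: ",
         paste(unique(cls[is.na(rank)]), collapse = ", "))
  if (!"start_pos" %in% names(candidates)) candidates$start_pos <- NA_real_
  top <- which(rank == min(rank))
  labels <- candidate_label(cls[top], candidates$parent_gene[top],
                            candidates$start_pos[top], bin_size)
  win <- top[order(labels, method = "radix")[1]]
  list(label = candidate_label(cls[win], candidates$parent_gene[win],
                               candidates$start_pos[win], bin_size),
       rna_class = cls[win])
}

#' Collapse sequence-level counts to annotation labels
#'
#' Each sequence is resolved to one annotation label via
#' [resolve_assignment()]; counts of all sequences sharing a label are
#' summed. Total reads per sample are conserved.
#'
#' @param records a `seq_records` object (see [seq_records()]).
#' @param sample_meta data frame with `sample_id`, `donor_id`, `component`
#'   (and optionally `is_whole_blood`) for the count columns.
#' @param bin_size bin width for rRNA/YRNA labels.
#' @return An [srna_set()] in `reads` units with a feature class map.
#' @export
collapse_counts <- function(records, sample_meta, bin_size = 25) {
  stopifnot(inherits(records, "seq_records"))
  asn <- records$assignments
  byseq <- split(seq_len(nrow(asn)), asn$seq_id)
  ids <- rownames(records$counts)
  res <- lapply(ids, function(sid) {
    rows <- byseq[[sid]]
    if (is.null(rows)) stop("sequence without candidates: ", sid)
    resolve_assignment(asn[rows, , drop = FALSE], bin_size)
  })
  labels <- vapply(res, `[[`, character(1), "label")
  classes <- vapply(res, `[[`, character(1), "rna_class")
  mat <- rowsum(records$counts, group = labels, reorder = TRUE)
  class_map <- classes[!duplicated(labels)]
  names(class_map) <- labels[!duplicated(labels)]
  conflicting <- tapply(classes, labels, function(z) length(unique(z)) > 1L)
  if (any(conflicting))
    warning("label(s) resolved from more than one class: ",
            paste(names(conflicting)[conflicting], collapse = ", "))
  srna_set(mat, sample_meta, units = "reads",
           classes = class_map[rownames(mat)])
}

#' Sequence-level small RNA records
#'
#' Pre-collapse unit of the pipeline: candidate annotations per sequence
#' plus per-sample read counts.
#'
#' @param assignments data frame with columns `seq_id`, `length_nt`,
#'   `rna_class`, `parent_gene`, `start_pos` (NA allowed outside
#'   rRNA/YRNA); one row per candidate, several rows per sequence allowed.
#' @param counts integer matrix, sequences in rows (row names = `seq_id`),
#'   samples in columns.
#' @return An object of class `seq_records`.
#' @export
seq_records <- function(assignments, counts) {
  req <- c("seq_id", "length_nt", "rna_class", "parent_gene", "start_pos")
  miss <- setdiff(req, names(assignments))
  if (length(miss))
    stop("`assignments` lacks column(s): ", paste(miss, collapse = ", "))
  if (any(assignments$length_nt < 1)) stop("`length_nt` must be >= 1")
  if (is.null(rownames(counts))) stop("`counts` needs seq_id row names")
  orphan <- setdiff(rownames(counts), assignments$seq_id)
  if (length(orphan))
    stop("sequences without candidates: ", paste(orphan, collapse = ", "))
  if (any(counts < 0)) stop("negative read counts")
  structure(list(assignments = assignments, counts = counts),
            class = "seq_records")
}

#' @export
print.seq_records <- function(x, ...) {
  cat(sprintf("seq_records: %d sequences, %d candidate rows, %d samples\n",
              nrow(x$counts), nrow(x$assignments), ncol(x$counts)))
  invisible(x)
}
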