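#' Read gene intervals from BED or GFF
#'
#' Parses gene annotation intervals with their native coordinate
#' conventions (BED: 0-based half-open; GFF3: 1-based closed) via
#' `rtracklayer::import()`, which converts both to the 1-based closed
#' `GRanges` representation used internally. Gene identifiers are taken
#' from the `name` (BED) / `ID` or `gene_id` (GFF) field, falling back to
#' `interval_<i>` in file order.
#'
#' @param path Annotation file (`.bed`, `.gff`, `.gff3`).
#' @param format `"auto"`, `"bed"` or `"gff3"`.
#' @return A `GRanges` with a `gene_id` metadata column, in file order.
#' @export
read_annotation <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  }
  gr <- rtracklayer::import(path, format = if (format == "bed") "BED" else
    "GFF3")
  ids <- if (format == "bed") {
    gr$name
  } else {
    id <- gr$ID
    if (is.null(id)) id <- gr$gene_id
    if (!is.null(id)) as.character(id) else NULL
  }
  if (is.null(ids) || anyNA(ids)) {
    ids <- paste0("interval_", seq_along(gr))
  }
  if (anyDuplicated(ids)) {
    stop("gene ids in ", path, " are not unique", call. = FALSE)
  }
  gr$gene_id <- ids
  S4Vectors::metadata(gr)$coord_convention <-
    if (format == "bed") "0-based" else "1-based"
  gr
}

#' Assign loci to gene groups by position
#'
#' Maps each locus to the gene interval containing it. A locus inside
#' several (overlapping) genes is assigned to the first gene in file
#' order, with a warning. Loci contained in no gene are either kept as
#' per-locus singleton groups or dropped.
#'
#' @param loci Data frame with columns `locus_id`, `chrom`, `pos`. The
#'   position is interpreted in the annotation's own coordinate
#'   convention (`pos_convention = "annotation"`, the default): 0-based
#'   against BED intervals, 1-based against GFF. Pass `"1-based"` or
#'   `"0-based"` to declare the locus convention explicitly (e.g.
#'   `"1-based"` for VCF POS values regardless of annotation format).
#' @param annotation A `GRanges` from [read_annotation()] (stored 1-based
#'   closed, with the source convention in its metadata).
#' @param pos_convention Coordinate convention of `loci$pos`; see above.
#' @param unassigned Policy for loci outside every gene: `"singleton"`
#'   (default) gives each its own group named after the locus; `"drop"`
#'   removes them.
#' @param flank Extend every gene by this many bases on both sides before
#'   matching. Default 0 (strict containment).
#' @return A tibble (`locus_id`, `group_id`) covering the retained loci.
#' @export
assign_groups <- function(loci, annotation,
                          unassigned = c("singleton", "drop"), flank = 0,
                          pos_convention = c("annotation", "1-based",
                                             "0-based")) {
  unassigned <- match.arg(unassigned)
  pos_convention <- match.arg(pos_convention)
  stopifnot(is.data.frame(loci),
            all(c("locus_id", "chrom", "pos") %in% names(loci)))
  if (pos_convention == "annotation") {
    pos_convention <- S4Vectors::metadata(annotation)$coord_convention %||%
      "1-based"
  }
  pos <- loci$pos + if (pos_convention == "0-based") 1L else 0L
  ann <- annotation
  if (flank > 0) {
    ann <- GenomicRanges::resize(
      ann, width = GenomicRanges::width(ann) + 2 * flank, fix = "center")
  }
  q <- GenomicRanges::GRanges(
    seqnames = as.character(loci$chrom),
    ranges = IRanges::IRanges(start = pos, width = 1L))
  hits <- GenomicRanges::findOverlaps(q, ann)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  if (anyDuplicated(qh)) {
    warning("loci overlapping several genes assigned to the first in ",
            "file order", call. = FALSE)
    first <- !duplicated(qh)
    qh <- qh[first]
    sh <- sh[first]
  }
  group <- rep(NA_character_, nrow(loci))
  group[qh] <- ann$gene_id[sh]
  out <- tibble::tibble(locus_id = as.character(loci$locus_id),
                        group_id = group)
  if (unassigned == "drop") {
    out <- out[!is.na(out$group_id), ]
  } else {
    miss <- is.na(out$group_id)
    out$group_id[miss] <- out$locus_id[miss]
  }
  out
}
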