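## Labeling DERs by their position relative to the nearest annotation(s).
## Seven classes: antisense, upstream, downstream, inside, overlapping_5prime,
## overlapping_3prime, overlapping_both.

#' Read annotations from GFF3/GTF
#'
#' Thin wrapper over [rtracklayer::import()] keeping records of the chosen
#' feature type(s) and normalizing the identifier attribute into a
#' `feature_id` metadata column.
#'
#' @param path GFF3 or GTF file.
#' @param feature_type feature type(s) to keep (default `"gene"`); `NULL`
#'   keeps everything.
#' @param id_attribute attribute carrying the identifier; defaults to `ID`
#'   (GFF3) falling back to `gene_id` (GTF) then to `Name`.
#' @return a stranded `GRanges` with a `feature_id` column.
#' @export
read_annotation <- function(path, feature_type = "gene", id_attribute = NULL) {
  gr <- rtracklayer::import(path)
  if (!is.null(feature_type) && "type" %in% names(mcols(gr)))
    gr <- gr[as.character(gr$type) %in% feature_type]
  keys <- if (!is.null(id_attribute)) id_attribute else c("ID", "gene_id", "Name")
  id <- rep(NA_character_, length(gr))
  for (k in keys) {
    if (k %in% names(mcols(gr))) {
      v <- as.character(mcols(gr)[[k]])
      id[is.na(id) & !is.na(v)] <- v[is.na(id) & !is.na(v)]
    }
  }
  id[is.na(id)] <- paste0("feature_", which(is.na(id)))
  mcols(gr)$feature_id <- id
  gr
}

.classify_pair <- function(der, anno) {
  ds <- start(der); de <- end(der)
  as_ <- start(anno); ae <- end(anno)
  der_strand <- as.character(strand(der))
  anno_strand <- as.character(strand(anno))
  overlap <- ds <= ae && de >= as_
  if (overlap) {
    if (der_strand != anno_strand) return("antisense")
    ## crossing is strict: a shared endpoint does not cross the boundary
    if (anno_strand == "+") {
      cross5 <- ds < as_; cross3 <- de > ae
    } else {
      cross5 <- de > ae; cross3 <- ds < as_
    }
    if (cross5 && cross3) return("overlapping_both")
    if (cross5) return("overlapping_5prime")
    if (cross3) return("overlapping_3prime")
    return("inside")
  }
  ## no overlap: position relative to the annotation's 5' side
  der_left <- de < as_
  if (anno_strand == "+") {
    if (der_left) "upstream" else "downstream"
  } else {
    if (der_left) "downstream" else "upstream"
  }
}

#' Label DERs by their nearest annotation(s)
#'
#' For each DER the minimal-distance annotation(s) are found (strand is
#' ignored for the nearest-neighbour search; overlap means distance 0), and
#' each (DER, annotation) pair receives exactly one of seven labels:
#' `inside` (same-strand DER contained in the annotation, shared endpoints
#' included), `overlapping_5prime` / `overlapping_3prime` (the DER crosses
#' exactly that strand-aware boundary of the annotation),
#' `overlapping_both`, `antisense` (opposite-strand overlap), or
#' `upstream` / `downstream` (no overlap, on the annotation's 5' / 3' side).
#' Distance ties produce one row per tying annotation.
#'
#' @param ders a stranded `GRanges` of DERs.
#' @param annotations a stranded `GRanges` with a `feature_id` column (see
#'   [read_annotation()]).
#' @return a data.frame with columns `der_id` (index into `ders`),
#'   `feature_id`, `label`, `distance` (0 when overlapping) and
#'   `strand_mismatch` (`TRUE` when a non-overlapping neighbour lies on the
#'   other strand).
#' @export
annotate_nearest <- function(ders, annotations) {
  if (length(annotations) == 0L) {
    return(data.frame(der_id = seq_along(ders),
                      feature_id = "no_annotation",
                      label = "no_annotation",
                      distance = NA_integer_,
                      strand_mismatch = NA))
  }
  if (is.null(mcols(annotations)$feature_id))
    mcols(annotations)$feature_id <- paste0("feature_", seq_along(annotations))
  out <- vector("list", length(ders))
  for (i in seq_along(ders)) {
    der <- ders[i]
    same_chr <- as.character(seqnames(annotations)) == as.character(seqnames(der))
    if (!any(same_chr)) {
      out[[i]] <- data.frame(der_id = i, feature_id = "no_annotation",
                             label = "no_annotation", distance = NA_integer_,
                             strand_mismatch = NA)
      next
    }
    annos <- annotations[same_chr]
    d <- GenomicRanges::distance(rep(GenomicRanges::granges(der), length(annos)),
                                 GenomicRanges::granges(annos),
                                 ignore.strand = TRUE)
    ## distance() is 0 for adjacent ranges too; overlap handled in classifier
    nearest <- which(d == min(d))
    rows <- lapply(nearest, function(j) {
      anno <- annos[j]
      lab <- .classify_pair(der, anno)
      data.frame(
        der_id = i,
        feature_id = mcols(anno)$feature_id,
        label = lab,
        distance = as.integer(d[j]),
        strand_mismatch = !(lab %in% c("antisense")) &&
          as.character(strand(der)) != as.character(strand(anno))
      )
    })
    out[[i]] <- do.call(rbind, rows)
  }
  do.call(rbind, out)
}
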