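## Genome-browser exports: BED / GFF3 / bedGraph tracks plus an IGV 2.x
## session XML referencing them with relative paths.

.round_score <- function(x, digits) round(x, digits)

.write_gff3 <- function(gr, path) {
  if (length(gr) == 0L) {
    mcols(gr) <- NULL   # rtracklayer rejects empty objects with metadata
  } else {
    mcols(gr)$source <- rep("derseg", length(gr))
  }
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Export all result tracks and an IGV session
#'
#' Writes, under `out_dir`: GFF3 files for DERs, non-DER segments and the
#' full segmentation; a BED6 of the segmentation; per-condition bedGraphs of
#' the replicate-mean `log2(coverage + 1)` per strand; per-strand bedGraphs
#' of the per-base log2-FC; and an IGV session XML listing every track with
#' a relative path. DER features carry a `color` attribute (up-regulated /
#' down-regulated / neutral).
#'
#' @param fit a [derseg()] object.
#' @param out_dir output directory (created if needed).
#' @param genome genome identifier written in the IGV session.
#' @param colors named list with `up`, `down`, `neutral` RGB strings.
#' @param digits number of decimal digits for bedGraph / score values.
#' @return an object of class `export_bundle`: named list of created paths.
#' @export
write_tracks <- function(fit, out_dir, genome = "custom",
                         colors = list(up = "0,160,80", down = "128,0,160",
                                       neutral = "150,150,150"),
                         digits = 6) {
  stopifnot(inherits(fit, "derseg"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  }
  paths <- list()

  segs <- fit$segments
  res <- fit$results
  der <- res$der %in% TRUE

  seg_gr <- GenomicRanges::granges(segs)
  mcols(seg_gr)$score <- .round_score(res$log2FoldChange, digits)
  mcols(seg_gr)$color <- ifelse(
    der & res$log2FoldChange > 0, colors$up,
    ifelse(der, colors$down, colors$neutral)
  )
  o <- order(as.factor(seqnames(seg_gr)), start(seg_gr), end(seg_gr))
  seg_gr <- seg_gr[o]
  der <- der[o]
  mcols(seg_gr)$ID <- sprintf("segment_%03d", seq_along(seg_gr))
  paths$segmentation_gff3 <- file.path(out_dir, "segmentation.gff3")
  .write_gff3(seg_gr, paths$segmentation_gff3)

  paths$segmentation_bed <- file.path(out_dir, "segmentation.bed")
  bed_gr <- seg_gr
  names(bed_gr) <- mcols(bed_gr)$ID
  ## BED scores must be numeric; keep the per-segment mean log2-FC
  rtracklayer::export(bed_gr, paths$segmentation_bed, format = "bed")

  paths$der_gff3 <- file.path(out_dir, "DER.gff3")
  .write_gff3(seg_gr[der], paths$der_gff3)
  paths$not_der_gff3 <- file.path(out_dir, "not_DER.gff3")
  .write_gff3(seg_gr[!der], paths$not_der_gff3)

  w <- fit$window
  per_base <- function(values) {
    gr <- GenomicRanges::GRanges(seqnames(w),
                                 IRanges::IRanges(start(w):end(w), width = 1))
    mcols(gr)$score <- .round_score(values, digits)
    ## collapse runs of equal score for compact bedGraph
    r <- S4Vectors::Rle(mcols(gr)$score)
    starts <- start(w) + cumsum(c(0L, S4Vectors::runLength(r)))
    out <- GenomicRanges::GRanges(
      seqnames(w),
      IRanges::IRanges(starts[-length(starts)],
                       starts[-1] - 1L)
    )
    mcols(out)$score <- S4Vectors::runValue(r)
    out
  }
  for (s in names(fit$profiles)) {
    tag <- if (s == "+") "fwd" else "rev"
    pr <- fit$profiles[[s]]
    for (cond in names(pr$mean_log2_cov)) {
      p <- file.path(out_dir, sprintf("log2_cov_%s_%s.bedGraph", cond, tag))
      rtracklayer::export(per_base(pr$mean_log2_cov[[cond]]), p,
                          format = "bedGraph")
      paths[[sprintf("log2_cov_%s_%s", cond, tag)]] <- p
    }
    p <- file.path(out_dir, sprintf("log2_fc_%s.bedGraph", tag))
    rtracklayer::export(per_base(pr$log2_fc), p, format = "bedGraph")
    paths[[sprintf("log2_fc_%s", tag)]] <- p
  }

  paths$igv_session <- file.path(out_dir, "igv_session.xml")
  write_igv_session(unlist(paths[names(paths) != "igv_session"]),
                    paths$igv_session, genome = genome)

  structure(paths, class = "export_bundle")
}

#' Write an IGV 2.x session XML
#'
#' Produces a `Session/Resources/Panel` document whose `Resource` elements
#' reference the given track files by paths relative to the session file's
#' directory.
#'
#' @param track_paths character vector of track file paths.
#' @param out_path session XML path.
#' @param genome genome identifier.
#' @return `out_path`, invisibly.
#' @export
write_igv_session <- function(track_paths, out_path, genome = "custom") {
  rel <- vapply(track_paths, function(p) {
    if (dirname(p) == dirname(out_path)) basename(p) else p
  }, character(1))
  doc <- xml2::xml_new_root("Session", genome = genome, version = "8")
  resources <- xml2::xml_add_child(doc, "Resources")
  for (p in rel) xml2::xml_add_child(resources, "Resource", path = p)
  panel <- xml2::xml_add_child(doc, "Panel", name = "DataPanel")
  for (p in rel) xml2::xml_add_child(panel, "Track", id = p, name = basename(p))
  xml2::write_xml(doc, out_path)
  invisible(out_path)
}

#' Write the DEA result table as TSV
#'
#' Columns: `chrom`, `start`, `end`, `strand`, `width`, `baseMean`,
#' `log2FoldChange`, `lfcSE`, `pvalue`, `padj`, `der`, `fdp_bound`, plus any
#' annotation label columns present.
#'
#' @param fit a [derseg()] object.
#' @param path output file.
#' @export
write_results <- function(fit, path) {
  write.table(fit$results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
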