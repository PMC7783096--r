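#' @title Gene models, tandem clusters and intron statistics
#' @name genome_map
#' @description
#' Maps family genes onto chromosomes and scaffolds, detects tandem
#' duplication clusters under a configurable proximity rule, and counts
#' introns.  Coordinates are 1-based inclusive throughout, as in GFF3.
NULL

#' Read gene models from a GFF3 file
#'
#' Parses `gene` and `exon` features (other types are ignored) using
#' rtracklayer and assembles one record per gene with its sorted exon
#' spans.  Exons are attached to genes through their `Parent` chain or,
#' failing that, by coordinate containment on the same seqid.
#'
#' @param path GFF3 file path.
#' @return data.frame with columns id, seqid, start, end, strand and a
#'   list-column `exons` of two-column matrices (start, end).
#' @export
read_gff <- function(path) {
  # friendly coordinate sanity check before handing to the parser
  raw <- readLines(path)
  body <- raw[!startsWith(raw, "#") & nzchar(raw)]
  if (length(body)) {
    f <- strsplit(body, "\t")
    bad <- which(vapply(f, function(x)
      length(x) >= 5 && suppressWarnings(
        as.numeric(x[5]) < as.numeric(x[4])), TRUE))
    if (length(bad))
      stop("malformed coordinates (end < start) in feature: ",
           sub(".*(ID|Parent)=([^;]+).*", "\\2", f[[bad[1]]][9]))
  }
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  is_gene <- md$type == "gene"
  is_exon <- md$type == "exon"
  gid <- as.character(md$ID)
  genes <- data.frame(
    id = gid[is_gene],
    seqid = as.character(GenomicRanges::seqnames(gr))[is_gene],
    start = GenomicRanges::start(gr)[is_gene],
    end = GenomicRanges::end(gr)[is_gene],
    strand = as.character(GenomicRanges::strand(gr))[is_gene],
    stringsAsFactors = FALSE)
  parent <- vapply(as.list(md$Parent), function(p)
    if (length(p)) as.character(p[1]) else NA_character_, "")
  # walk mRNA -> gene so exons parented to transcripts still resolve
  id2parent <- stats::setNames(parent, gid)
  resolve <- function(p) {
    while (!is.na(p) && !(p %in% genes$id) && p %in% names(id2parent))
      p <- id2parent[[p]]
    p
  }
  ex <- data.frame(
    seqid = as.character(GenomicRanges::seqnames(gr))[is_exon],
    start = GenomicRanges::start(gr)[is_exon],
    end = GenomicRanges::end(gr)[is_exon],
    parent = vapply(parent[is_exon], resolve, ""),
    stringsAsFactors = FALSE)
  genes$exons <- lapply(seq_len(nrow(genes)), function(i) {
    e <- ex[!is.na(ex$parent) & ex$parent == genes$id[i], , drop = FALSE]
    if (nrow(e) == 0L)   # fall back to containment
      e <- ex[ex$seqid == genes$seqid[i] & ex$start >= genes$start[i] &
                ex$end <= genes$end[i] & is.na(ex$parent), , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    if (nrow(e) && (min(e$start) < genes$start[i] ||
                    max(e$end) > genes$end[i]))
      stop("exon outside parent span for gene ", genes$id[i])
    cbind(start = e$start, end = e$end)
  })
  genes[order(genes$seqid, genes$start), ]
}

#' Count introns of a gene model
#'
#' Introns are simply the gaps between consecutive exons:
#' `exon count - 1`.
#'
#' @param gene one row of the data.frame from [read_gff()] (or any
#'   list with an `exons` matrix).
#' @return integer intron count.
#' @export
count_introns <- function(gene) {
  ex <- if (is.data.frame(gene)) gene$exons[[1]] else gene$exons
  n <- if (is.matrix(ex)) nrow(ex) else length(ex)
  if (n == 0L) stop("gene has zero exons; intron count undefined")
  n - 1L
}

#' Detect tandem duplication clusters
#'
#' Per seqid, family genes sorted by start are chained while the number
#' of intervening non-family gene models is at most `max_intervening`
#' and the start-to-start gap is at most `max_gap`.  Maximal chains
#' with at least two members become clusters.  Cluster ids follow the
#' convention `C<chromosome number>.<cluster number>` with clusters
#' numbered per seqid in positional order; strand is ignored (tandem
#' repeats may lie in the same or reverse orientation).
#'
#' @param family_ids character vector of family gene ids.
#' @param genes gene models data.frame from [read_gff()].
#' @param max_intervening allowed non-family gene models between
#'   consecutive members (default 8).
#' @param max_gap allowed start-to-start distance in bp (default
#'   250000).  Both defaults are documented surrogates for the
#'   proximity rule used in the plant gene-family literature.
#' @return data.frame (cluster_id, seqid, members, n, span_bp) with
#'   `members` a comma-separated id list ordered by start.
#' @export
detect_tandem_clusters <- function(family_ids, genes,
                                   max_intervening = 8L,
                                   max_gap = 250000L) {
  missing <- setdiff(family_ids, genes$id)
  if (length(missing))
    stop("family id(s) absent from gene models: ",
         paste(missing, collapse = ", "))
  out <- list()
  for (sq in unique(genes$seqid)) {
    g <- genes[genes$seqid == sq, , drop = FALSE]
    g <- g[order(g$start), , drop = FALSE]
    fam_idx <- which(g$id %in% family_ids)
    if (length(fam_idx) < 2L) next
    chain <- list(fam_idx[1])
    for (k in seq_along(fam_idx)[-1]) {
      prev <- fam_idx[k - 1L]; cur <- fam_idx[k]
      intervening <- cur - prev - 1L
      gap <- g$start[cur] - g$start[prev]
      if (intervening <= max_intervening && gap <= max_gap) {
        chain[[length(chain)]] <- c(chain[[length(chain)]], cur)
      } else {
        chain[[length(chain) + 1L]] <- cur
      }
    }
    num <- 0L
    chrnum <- sub("^Chr0?", "", sq)
    for (ch in chain) {
      if (length(ch) < 2L) next
      num <- num + 1L
      out[[length(out) + 1L]] <- data.frame(
        cluster_id = sprintf("C%s.%d", chrnum, num),
        seqid = sq,
        members = paste(g$id[ch], collapse = ","),
        n = length(ch),
        span_bp = max(g$end[ch]) - min(g$start[ch]) + 1L)
    }
  }
  if (length(out) == 0L)
    return(data.frame(cluster_id = character(0), seqid = character(0),
                      members = character(0), n = integer(0),
                      span_bp = integer(0)))
  do.call(rbind, out)
}

#' Chromosome vs scaffold localisation summary
#'
#' Classifies seqids by prefix (`Chr` = chromosome, anything else =
#' scaffold) and reports counts plus the percent of genes on
#' chromosomes, rounded to the nearest integer as conventionally
#' reported (e.g. 127/146 = 87%).
#'
#' @param genes gene models data.frame (or any data.frame with a
#'   `seqid` column), typically subset to the family.
#' @param chrom_prefix regular expression anchoring chromosome-type
#'   seqids.
#' @return list with `chromosomal`, `scaffold`, `percent_chromosomal`.
#' @export
localization_summary <- function(genes, chrom_prefix = "^Chr") {
  on_chr <- grepl(chrom_prefix, genes$seqid)
  list(chromosomal = sum(on_chr),
       scaffold = sum(!on_chr),
       percent_chromosomal = round(100 * mean(on_chr)))
}
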