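#' Specify a synthetic chromosome layout
#'
#' Declares the chromosomes, the tandem clusters to plant (each on a
#' named chromosome with a member count, a per-step intervening-gene
#' count and a per-step bp gap), and the fraction of family genes to
#' place on scaffolds.
#'
#' @param n_chromosomes number of chromosomes, named `Chr01` ...
#' @param chrom_length length of each chromosome in bp (recycled).
#' @param clusters data.frame with columns `chrom`, `n` (members,
#'   >= 2), `intervening` (non-family genes between consecutive
#'   members) and `gap_bp` (start-to-start distance between
#'   consecutive members).
#' @param scaffold_fraction fraction of family genes placed on
#'   scaffolds (`scaffold_1` ...) rather than chromosomes.
#' @param exon_range integer range the per-gene exon count is drawn
#'   from.
#' @return object of class `layout_spec`.
#' @export
layout_spec <- function(n_chromosomes = 19L,
                        chrom_length = 5e6,
                        clusters = data.frame(
                          chrom = c("Chr01", "Chr02", "Chr05"),
                          n = c(3L, 2L, 4L),
                          intervening = c(1L, 0L, 2L),
                          gap_bp = c(60000L, 15000L, 80000L)),
                        scaffold_fraction = 0.13,
                        exon_range = c(1L, 27L)) {
  stopifnot(n_chromosomes >= 1L)
  if (nrow(clusters)) {
    if (any(clusters$n < 2L)) stop("planted clusters need >= 2 members")
    if (any(clusters$gap_bp <= 0)) stop("cluster gaps must be positive")
    if (any(clusters$gap_bp < 7000))
      stop("cluster gap_bp must be >= 7000 (genes are 2-6 kb long)")
    chroms <- sprintf("Chr%02d", seq_len(n_chromosomes))
    bad <- setdiff(clusters$chrom, chroms)
    if (length(bad)) stop("cluster chromosome(s) not declared: ",
                          paste(bad, collapse = ", "))
  }
  if (scaffold_fraction < 0 || scaffold_fraction > 1)
    stop("scaffold_fraction must lie in [0, 1]")
  structure(list(n_chromosomes = as.integer(n_chromosomes),
                 chrom_length = rep_len(chrom_length, n_chromosomes),
                 clusters = clusters,
                 scaffold_fraction = scaffold_fraction,
                 exon_range = as.integer(exon_range)),
            class = "layout_spec")
}

.gene_gff_lines <- function(id, seqid, start, end, strand, exons) {
  c(sprintf("%s\tfamcensus\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
            seqid, start, end, strand, id),
    sprintf("%s\tfamcensus\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.1;Parent=%s",
            seqid, start, end, strand, id, id),
    sprintf("%s\tfamcensus\texon\t%d\t%d\t.\t%s\t.\tID=%s.1.exon%d;Parent=%s.1",
            seqid, exons[, 1], exons[, 2], strand, id,
            seq_len(nrow(exons)), id))
}

# split [start, end] into n_exons non-overlapping sorted spans
.make_exons <- function(start, end, n_exons) {
  len <- end - start + 1L
  if (n_exons == 1L) return(cbind(start = start, end = end))
  cuts <- sort(sample(seq_len(len - 1L), 2L * n_exons - 1L))
  bounds <- c(0L, cuts, len)
  spans <- cbind(start + bounds[seq(1, 2 * n_exons, 2)],
                 start + bounds[seq(2, 2 * n_exons, 2)] - 1L)
  spans[1, 1] <- start; spans[n_exons, 2] <- end
  colnames(spans) <- c("start", "end")
  spans
}

#' Generate synthetic gene models (GFF3) with planted tandem clusters
#'
#' Lays family genes out on chromosomes and scaffolds.  Genes assigned
#' to a planted cluster satisfy the cluster's intervening-gene and gap
#' bounds between consecutive members; family genes outside clusters
#' are isolated, i.e. they violate both bounds relative to any family
#' neighbour.  Background genes fill the intervening slots and the
#' space between family loci.
#'
#' @param family_ids ids of family genes (e.g. the `protein_id` column
#'   of [generate_proteome()] truth), placed in order.
#' @param layout a [layout_spec()].
#' @param seed integer seed.
#' @param isolation_intervening,isolation_gap_bp separation applied
#'   around non-cluster family genes; must exceed any clustering rule
#'   you intend to test (defaults: 12 intervening genes, 400 kb).
#' @return list with `gff` (character vector of GFF3 lines), `genes`
#'   (data.frame id, seqid, start, end, strand, n_exons), and
#'   `clusters` (truth data.frame cluster_id, seqid, members).
#' @export
generate_gene_models <- function(family_ids, layout = layout_spec(),
                                 seed = 1L,
                                 isolation_intervening = 12L,
                                 isolation_gap_bp = 400000L) {
  stopifnot(inherits(layout, "layout_spec"))
  need <- sum(layout$clusters$n)
  if (need > length(family_ids))
    stop("planted clusters demand ", need, " family genes but only ",
         length(family_ids), " are available")
  with_seed(seed, {
    chroms <- sprintf("Chr%02d", seq_len(layout$n_chromosomes))
    n_scaffold <- round(layout$scaffold_fraction * length(family_ids))
    if (n_scaffold > length(family_ids) - need)
      stop("scaffold_fraction too high: cluster members must stay on ",
           "chromosomes")
    gene_len <- function() sample(2000:6000, 1L)
    bg_i <- 0L
    rows <- list(); gff <- character(0); truth_clusters <- list()
    emit <- function(id, seqid, start, strand, n_exons) {
      end <- start + gene_len() - 1L
      exons <- .make_exons(start, end, n_exons)
      rows[[length(rows) + 1L]] <<- data.frame(
        id = id, seqid = seqid, start = start, end = end,
        strand = strand, n_exons = n_exons)
      gff <<- c(gff, .gene_gff_lines(id, seqid, start, end, strand, exons))
      end
    }
    emit_bg <- function(seqid, start) {
      bg_i <<- bg_i + 1L
      emit(sprintf("BG%04d", bg_i), seqid, start,
           sample(c("+", "-"), 1L), sample(1:8, 1L))
    }
    fam_exons <- function() sample(layout$exon_range[1]:layout$exon_range[2], 1L)
    fam_queue <- family_ids
    cursor <- stats::setNames(rep(50000L, length(chroms)), chroms)

    # planted clusters first
    if (nrow(layout$clusters)) for (ci in seq_len(nrow(layout$clusters))) {
      cl <- layout$clusters[ci, ]
      sq <- cl$chrom
      members <- fam_queue[seq_len(cl$n)]
      fam_queue <- fam_queue[-seq_len(cl$n)]
      pos <- cursor[[sq]]
      for (mi in seq_len(cl$n)) {
        emit(members[mi], sq, pos, sample(c("+", "-"), 1L), fam_exons())
        if (mi < cl$n) {
          nxt <- pos + cl$gap_bp     # start-to-start gap bound
          if (cl$intervening > 0L) {
            slot <- pos + 6500L
            for (k in seq_len(cl$intervening)) {
              if (slot + 7000L >= nxt) break
              emit_bg(sq, slot)
              slot <- slot + 7000L
            }
          }
          pos <- nxt
        }
      }
      cursor[[sq]] <- pos + isolation_gap_bp
      for (k in seq_len(isolation_intervening)) {
        emit_bg(sq, pos + 20000L + k * 9000L)
      }
      n_before <- sum(vapply(truth_clusters, function(x)
        x$seqid == sq, TRUE))
      truth_clusters[[length(truth_clusters) + 1L]] <- data.frame(
        cluster_id = sprintf("C%s.%d", sub("^Chr0?", "", sq), n_before + 1L),
        seqid = sq, members = paste(members, collapse = ","),
        n = cl$n)
      if (cursor[[sq]] > layout$chrom_length[match(sq, chroms)])
        stop("chromosome ", sq, " overflows its declared length")
    }

    # isolated family genes on chromosomes
    n_iso_chr <- length(fam_queue) - n_scaffold
    for (k in seq_len(max(n_iso_chr, 0L))) {
      sq <- chroms[1L + (k - 1L) %% length(chroms)]
      pos <- cursor[[sq]]
      for (j in seq_len(isolation_intervening)) {
        emit_bg(sq, pos); pos <- pos + 9000L
      }
      emit(fam_queue[1L], sq, pos, sample(c("+", "-"), 1L), fam_exons())
      fam_queue <- fam_queue[-1L]
      pos <- pos + 9000L
      for (j in seq_len(isolation_intervening)) {
        emit_bg(sq, pos); pos <- pos + 9000L
      }
      cursor[[sq]] <- pos + isolation_gap_bp
      if (cursor[[sq]] > layout$chrom_length[match(sq, chroms)])
        stop("chromosome ", sq, " overflows its declared length")
    }

    # scaffold-resident family genes, one per scaffold
    for (k in seq_len(n_scaffold)) {
      sq <- sprintf("scaffold_%d", k)
      emit(fam_queue[1L], sq, 10000L, sample(c("+", "-"), 1L), fam_exons())
      fam_queue <- fam_queue[-1L]
    }

    genes <- do.call(rbind, rows)
    header <- c("##gff-version 3",
                sprintf("##sequence-region %s 1 %d", chroms,
                        as.integer(layout$chrom_length)))
    list(gff = c(header, gff),
         genes = genes,
         clusters = if (length(truth_clusters))
           do.call(rbind, truth_clusters)
         else data.frame(cluster_id = character(0), seqid = character(0),
                         members = character(0), n = integer(0)))
  })
}
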