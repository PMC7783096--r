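# Shared fixtures, all generated in code.

# three-clade family whose MD regions carry the clade signal
three_clade_family <- function(genes_per_clade = 4L, seed = 11L) {
  spec <- family_spec(
    list(A = c("LRR", "MD", "TMD", "PK"),
         B = c("SP", "MLD", "TMD", "PK"),
         C = c("MD", "Kin")),
    genes_per_clade = genes_per_clade, background = 0L,
    clade_divergence = 0.1)
  generate_proteome(spec, seed = seed)
}

# ungapped pseudo-alignment from each protein's first MD region
md_alignment <- function(pr) {
  seqs <- read_fasta(pr$fasta)
  md <- pr$hits[pr$hits$token == "MD", ]
  md <- md[!duplicated(md$protein_id), ]
  aln <- do.call(rbind, lapply(seq_len(nrow(md)), function(i)
    strsplit(substr(seqs[[md$protein_id[i]]], md$start[i], md$end[i]),
             "")[[1]]))
  rownames(aln) <- md$protein_id
  aln
}

# profile series with one planted positively co-expressed module around
# each guide (4 partners each), everything else independent noise
planted_series <- function(n_genes = 200L, n_pos = 50L, guides = "g001",
                           noise = 0.15, seed = 1L) {
  set.seed(seed)
  ids <- sprintf("g%03d", seq_len(n_genes))
  mat <- matrix(rnorm(n_genes * n_pos), n_genes, n_pos,
                dimnames = list(ids, NULL))
  free <- setdiff(ids, guides)
  truth <- list()
  for (g in guides) {
    partners <- free[1:4]; free <- free[-(1:4)]
    latent <- rnorm(n_pos, 0, 1.5)
    for (m in c(g, partners)) mat[m, ] <- latent + rnorm(n_pos, 0, noise)
    truth[[g]] <- partners
  }
  list(mat = mat, truth = truth)
}

edge_keys <- function(edges) {
  c(paste(edges$gene_a, edges$gene_b), paste(edges$gene_b, edges$gene_a))
}

# layout planting one cluster of each size on its own chromosome
sized_cluster_layout <- function(sizes = 2:11) {
  layout_spec(
    n_chromosomes = max(19L, length(sizes)),
    chrom_length = 8e6,
    clusters = data.frame(
      chrom = sprintf("Chr%02d", seq_along(sizes)),
      n = as.integer(sizes),
      intervening = rep_len(c(0L, 1L, 2L, 3L), length(sizes)),
      gap_bp = rep_len(c(15000L, 60000L, 120000L, 200000L),
                       length(sizes))),
    scaffold_fraction = 0)
}
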