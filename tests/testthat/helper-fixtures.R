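options(jsdmnet.quiet = TRUE)

# 2x2 count fixture used across io tests
tiny_counts <- function() {
  matrix(c(3, 1, 0, 2), 2, 2,
         dimnames = list(c("s1", "s2"), c("tA", "tB")))
}

tiny_table <- function() {
  community_table(tiny_counts(),
                  group = c(tA = "bacteria", tB = "fungi"),
                  trophic = c(tA = "heterotrophic", tB = "heterotrophic"))
}

write_counts_tsv <- function(counts, path = tempfile(fileext = ".tsv")) {
  df <- data.frame(sample_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_annotation_tsv <- function(taxa, group, trophic,
                                 path = tempfile(fileext = ".tsv")) {
  utils::write.table(
    data.frame(taxon_id = taxa, group = group, trophic = trophic),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# small three-edge network over annotated taxa
toy_network <- function() {
  edges <- data.frame(taxon_a = c("b1", "b1"), taxon_b = c("b2", "p1"),
                      median = c(0.5, -0.3), lower = c(0.2, -0.5),
                      upper = c(0.7, -0.1),
                      sign = c("positive", "negative"))
  ann <- data.frame(taxon_id = c("b1", "b2", "p1"),
                    group = c("bacteria", "bacteria", "small_eukaryote"),
                    trophic = c("heterotrophic", "heterotrophic", "photosynthetic"))
  build_network(edges, ann)
}

# null clr matrix: iid gaussian rows recentred to sum zero
null_clr <- function(n, p, seed = 1) {
  set.seed(seed)
  Y <- matrix(rnorm(n * p), n, p,
              dimnames = list(paste0("s", seq_len(n)), paste0("t", seq_len(p))))
  sweep(Y, 1, rowMeans(Y))
}
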