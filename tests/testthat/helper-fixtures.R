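# Programmatic fixtures shared across test files.

# small linear chain x -> v1 -> v2 -> v3, single genes
chain_graph <- function(len = 3) {
  ids <- c("x", sprintf("v%d", seq_len(len)))
  tibble::tibble(
    reaction_id = sprintf("Rc%d", seq_len(len)),
    source = ids[-length(ids)],
    target = ids[-1],
    gpr = sprintf("cg%d", seq_len(len)),
    pathways = "chain"
  ) |> metabolic_graph()
}

# expression matrix with fixed values for a gene set
expr_matrix <- function(genes, n_samples = 3, seed = 1) {
  set.seed(seed)
  m <- matrix(round(runif(length(genes) * n_samples, 0.5, 3), 3),
              nrow = length(genes),
              dimnames = list(genes, sprintf("s%d", seq_len(n_samples))))
  m
}

# minimal KGML document text
kgml_text <- function(reaction_type = "irreversible") {
  sprintf('<?xml version="1.0"?>
<pathway name="path:hsa00600" org="hsa" number="00600">
  <entry id="1" name="cpd:C00001" type="compound"/>
  <entry id="2" name="cpd:C00002" type="compound"/>
  <entry id="3" name="hsa:111 hsa:222" type="gene" reaction="rn:R00001"/>
  <reaction id="10" name="rn:R00001" type="%s">
    <substrate id="1" name="cpd:C00001"/>
    <product id="2" name="cpd:C00002"/>
  </reaction>
</pathway>', reaction_type)
}

write_kgml <- function(text, file = tempfile(fileext = ".xml")) {
  writeLines(text, file)
  file
}

# feature matrix (features x samples) with two well-separated sample blobs
two_blob_matrix <- function(n_per = 50, n_feat = 20, sep = 8, seed = 1) {
  set.seed(seed)
  a <- matrix(rnorm(n_feat * n_per), n_feat)
  b <- matrix(rnorm(n_feat * n_per, mean = sep), n_feat)
  m <- cbind(a, b)
  dimnames(m) <- list(sprintf("f%02d", seq_len(n_feat)),
                      sprintf("s%03d", seq_len(2 * n_per)))
  attr(m, "truth") <- rep(1:2, each = n_per)
  m
}
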