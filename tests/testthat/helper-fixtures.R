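# Shared miniature fixtures built in code.

# two-genus, four-species toy taxonomy
toyTaxonomy <- function() {
  data.frame(
    species = c("Pana_alpha", "Pana_beta", "Lutra_gamma", "Lutra_delta"),
    genus = c("Pana", "Pana", "Lutra", "Lutra"),
    family = c("Panidae", "Panidae", "Lutridae", "Lutridae"),
    order = c("Carnivora", "Carnivora", "Carnivora", "Carnivora"),
    class = "Mammalia", stringsAsFactors = FALSE)
}

# deterministic sequences of given length from a seeded alphabet walk
seqOf <- function(len, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
        collapse = "")
}

mutateAt <- function(seq, pos, to) {
  substr(seq, pos, pos) <- to
  seq
}

ad16S <- function() markerAmplicons("16S")[[1]]

# a curated-format reference db over the toy taxonomy: one distinct
# 93-nt insert per species, nPer accessions each
toyRefDb <- function(nPer = 2L) {
  tax <- toyTaxonomy()
  rows <- lapply(seq_len(nrow(tax)), function(i) {
    ins <- seqOf(93L, 100 + i)
    data.frame(accession = sprintf("ACC%03d", i * 10 + seq_len(nPer)),
               species = tax$species[i], marker = "16S", seq = ins,
               source = "local", stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

toyTree <- function(nPer = 1L) {
  attachReferences(buildTaxonomyTree(toyTaxonomy()), toyRefDb(nPer))
}
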