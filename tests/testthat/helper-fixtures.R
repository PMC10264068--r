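# Small in-code fixtures shared across test files.

myco_catalog <- function() {
  load_catalog(system.file("extdata", "catalog_mycobacteria.tsv",
                           package = "phanticodon"))
}

entero_catalog <- function() {
  load_catalog(system.file("extdata", "catalog_enterobacteria.tsv",
                           package = "phanticodon"))
}

# A well-formed 76-nt synthetic tRNA gene for an arbitrary key, built from
# the package's own generator via a one-key scenario.
make_gene_set <- function(isotypes, anticodons, seed = 11L) {
  scn <- scenario(seed = seed, n_phages = 1L,
                  host_keys = data.frame(isotype = isotypes,
                                         anticodon = anticodons,
                                         stringsAsFactors = FALSE),
                  targets = data.frame(isotype = character(),
                                       anticodon = character(),
                                       nuclease_name = character(),
                                       cleavage_bond = character(),
                                       motif = character(),
                                       avoided = logical(),
                                       mutate_at = integer(),
                                       stringsAsFactors = FALSE))
  generate_host_trnas(scn)$genes
}

write_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
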