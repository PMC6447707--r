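## Shared fixtures, memoised so expensive objects are built once per run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

fix_ref <- function() fixture("ref", reference_data)

fix_genomes <- function(seed = 1) {
  fixture(paste0("genomes", seed), function()
    lapply(default_genome_specs(), simulate_genome, seed = seed,
           ref = fix_ref()))
}

fix_contigs <- function(seed = 1) {
  fixture(paste0("contigs", seed), function()
    shear_contigs(fix_genomes(seed), n_per_genome = 150, seed = seed))
}

fix_annotation <- function(seed = 1) {
  fixture(paste0("ann", seed), function()
    annotate_contigs(fix_contigs(seed), ref = fix_ref()))
}

## quick constructor for a read with uniform quality
read_q <- function(bases, q, id = "r") {
  amplicon_read(id, bases, rep(q, nchar(bases)))
}

## minimal taxon_assignment with a fixed display label
fake_assignment <- function(display) {
  structure(list(confidences = NULL, accepted_rank = "genus",
                 display = display), class = "taxon_assignment")
}

## the six-genus presence/absence matrix transcribed from the reported
## gene content of the dominant genera
reported_gene_content <- function() {
  feats <- role_features()
  m <- matrix(FALSE, 6, length(feats),
              dimnames = list(c("Clostridium", "Paludibacter",
                                "Cloacibacterium", "Exiguobacterium",
                                "Acetivibrio", "Tolumonas"), feats))
  m["Clostridium", c("endoglucanase", "beta_glucosidase",
                     "six_phospho_beta_glucosidase", "pts_cel")] <- TRUE
  m["Paludibacter", c("endoglucanase", "beta_glucosidase",
                      "cellobiose_phosphorylase")] <- TRUE
  m["Cloacibacterium", c("beta_glucosidase",
                         "six_phospho_beta_glucosidase")] <- TRUE
  m["Exiguobacterium", c("beta_glucosidase", "six_phospho_beta_glucosidase",
                         "pts_cel")] <- TRUE
  m["Acetivibrio", c("beta_glucosidase", "six_phospho_beta_glucosidase",
                     "pts_cel")] <- TRUE
  m["Tolumonas", c("beta_glucosidase", "six_phospho_beta_glucosidase",
                   "pts_cel")] <- TRUE
  m
}
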