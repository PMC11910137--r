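# Shared small-scale synthetic fixtures, built in code at test time.

small_config <- function(n_strains = 6L, genus_partition = c(2L, 2L, 1L, 1L),
                         spectra = 20L, n_channels = 120L, seed = 3L, ...) {
  synthetic_config(n_strains = n_strains, genus_partition = genus_partition,
                   n_phyla = 2L, spectra_per_strain_per_stage = spectra,
                   grid = list(start = 600, stop = 1800,
                               n_channels = as.integer(n_channels)),
                   seed = seed, ...)
}

small_dataset <- local({
  cache <- new.env(parent = emptyenv())
  function(seed = 3L, ...) {
    key <- paste0("ds_", seed, "_", paste(deparse(list(...)), collapse = ""))
    if (is.null(cache[[key]])) {
      cfg <- small_config(seed = seed, ...)
      cache[[key]] <- generate_dataset(make_taxonomy(cfg), cfg)
    }
    cache[[key]]
  }
})

# tiny labelled dataset with hand-set values, for exact-arithmetic tests
toy_dataset <- function(ints = matrix(as.numeric(1:15), nrow = 3),
                        stages = c("Exp", "S1", "S2")) {
  scrs_dataset(grid = seq_len(ncol(ints)) * 10 + 500,
               intensities = ints,
               labels = data.frame(cell_id = paste0("c", seq_len(nrow(ints))),
                                   strain = paste0("s", seq_len(nrow(ints))),
                                   genus = "g1", phylum = "p1",
                                   stage = stages[seq_len(nrow(ints))]))
}
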