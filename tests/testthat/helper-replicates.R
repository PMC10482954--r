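# Memoized synthetic ACE replicates shared by the enhancement-recovery
# and preferential-denoising acceptance tests (the heavy computation runs
# once per test session).
ace_replicates <- local({
  cache <- NULL
  function(seeds = 1:10) {
    if (!is.null(cache)) return(cache)
    out <- lapply(seeds, function(s) {
      spec <- synthetic_spec(seed = s)
      fam <- generate_family(spec)
      truth_map <- build_dual_fold_map(
        as_contact_sets(fam$truth$dominant_pairs, L = spec$L, id = "dom"),
        as_contact_sets(fam$truth$alternative_pairs, L = spec$L,
                        id = "alt"))
      nested <- make_nested_msas(fam$msa)
      res <- run_ace(nested, reference_map = truth_map)
      truth_map$dominant_id <- determine_dominant(
        truth_map, res$superfamily_retained)
      list(fam = fam, map = truth_map, res = res)
    })
    cache <<- out
    out
  }
})
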