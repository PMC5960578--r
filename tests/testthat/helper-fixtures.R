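# Small in-code fixtures shared across test files.

# minimal single-triangle universe
tiny_tables <- function() {
  list(
    ld = association_table(data.frame(l = "l1", d = "d1"), "lncRNA-disease"),
    md = association_table(data.frame(m = "m1", d = "d1"), "miRNA-disease"),
    lm = association_table(data.frame(l = "l1", m = "m1"), "lncRNA-miRNA")
  )
}

# small planted dataset + fitted model, memoized per test run
small_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synthetic_config(n_diseases = 10, n_lncRNAs = 12, n_miRNAs = 11,
                              n_communities = 2, seed = 7)
      dat <- generate_lmpair_data(cfg)
      cache <<- suppressWarnings(
        lmpair_model(dat$lnc_disease, dat$mir_disease, dat$lnc_mir, dat$dag)
      )
    }
    cache
  }
})

# random association edge tables over small id universes
random_tables <- function(nd = 10, nl = 10, nm = 10, p = 0.3) {
  d <- sprintf("d%d", 1:nd)
  l <- sprintf("l%d", 1:nl)
  m <- sprintf("m%d", 1:nm)
  draw <- function(a, b, p) {
    grid <- expand.grid(left = a, right = b, stringsAsFactors = FALSE)
    grid[stats::runif(nrow(grid)) < p, , drop = FALSE]
  }
  list(ld = draw(l, d, p), md = draw(m, d, p), lm = draw(l, m, p))
}
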