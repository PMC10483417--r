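# Shared fixture builders. Everything is generated in code at test time;
# no stored binary fixtures.

# A small default fixture: 3 families x 2 kingdoms x 4 records plus the
# planted extras the tests need.
default_spec <- function(...) {
  fixture_spec(n_multifamily_proteins = 2, n_redundant_pairs = 7,
               n_multitaxon_conflicts = 2, cluster_sizes = c(4, 3, 3),
               n_with_ec = 5, n_with_pdb = 4, rng_seed = 20260925, ...)
}

# Generate a fixture into a self-cleaning temp dir.
make_fixture <- function(spec = default_spec(), env = parent.frame()) {
  dir <- withr::local_tempdir(.local_envir = env)
  generate_fixture(spec, dir)
}

# Build a store from a fixture's dump, closed automatically.
make_store <- function(gt, criteria = NULL, env = parent.frame()) {
  db <- withr::local_tempfile(fileext = ".db", .local_envir = env)
  store <- init_store(db)
  withr::defer(close_store(store), envir = env)
  dump <- parse_dump(gt$files[["dump"]])
  import_dump(store, dump, criteria)
  store
}

random_protein <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  paste(sample(aa, n, replace = TRUE), collapse = "")
}
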