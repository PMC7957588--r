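# Shared lazily-built fixtures (memoized per test run; everything is
# generated in code, nothing is read from disk beyond what the generators
# themselves write).

.fixture_cache <- new.env(parent = emptyenv())

tiny_fixture <- function() {
  if (is.null(.fixture_cache$tiny)) {
    .fixture_cache$tiny <- make_fixture("tiny", dir = tempfile("tinyfx"),
                                        seed = 101L)
  }
  .fixture_cache$tiny
}

tiny_run <- function() {
  if (is.null(.fixture_cache$tiny_run)) {
    fx <- tiny_fixture()
    dir <- tempfile("tinyrun")
    res <- run_pipeline(fx$config, dir)
    .fixture_cache$tiny_run <- list(res = res, dir = dir, fx = fx)
  }
  .fixture_cache$tiny_run
}

demo_run <- function() {
  if (is.null(.fixture_cache$demo_run)) {
    fx <- make_fixture("demo", dir = tempfile("demofx"), seed = 202L)
    dir <- tempfile("demorun")
    res <- run_pipeline(fx$config, dir)
    .fixture_cache$demo_run <- list(res = res, dir = dir, fx = fx)
  }
  .fixture_cache$demo_run
}

# a hand-built compliant stem-loop of length 100 with a 19-pair duplex and
# 2-nt 3' overhangs at both ends; structure supplied, so folding-engine-free
flat_hairpin <- function() {
  structure_str <- paste0(strrep("(", 24), strrep("(", 19), "..",
                          strrep(".", 10), strrep(")", 19), "..",
                          strrep(")", 24))
  list(
    sequence = strrep("ACGT", 25), # GC fraction exactly 0.5
    structure = structure_str,
    reads = data.frame(start = c(25L, 56L), end = c(45L, 76L),
                       max_count = c(50, 30)))
}
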