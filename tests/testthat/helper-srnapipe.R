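# Shared simulated fixtures, built once per test run and memoised.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

demo_ref <- function() cached("ref", build_reference(n_mirnas = 25,
                                                     n_other_loci = 4,
                                                     seed = 42))

demo_profile <- function(n_reads = 20000L, ...)
  sim_profile(demo_ref(), seed = 7, n_reads = n_reads, ...)

# One library with reads, for preprocessing/annotation tests.
demo_library <- function() cached("lib",
  simulate_library(demo_ref(), demo_profile(), seed = 11,
                   sample_name = "Q1N"))

demo_index <- function() cached("index", build_index(demo_ref()))

# Noise-free library (no low-quality reads) for exact recovery checks.
clean_library <- function() cached("clean_lib",
  simulate_library(demo_ref(), demo_profile(low_quality_fraction = 0),
                   seed = 13, sample_name = "S1T"))

# Phred+33 string of a constant score.
qual_string <- function(score, n) strrep(intToUtf8(score + 33L), n)

# A raw read: insert + adapter + random tail, at constant quality.
make_read <- function(id, insert, adapter, score = 38, read_length = 50,
                      tail = "ACGTACGTACGTACGTACGT") {
  seq <- substr(paste0(insert, adapter, tail), 1, read_length)
  data.frame(id = id, sequence = seq,
             quality = qual_string(score, nchar(seq)),
             stringsAsFactors = FALSE)
}
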