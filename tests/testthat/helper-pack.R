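# Shared fixture: one synthetic pack reused across test files (generation is
# deterministic, so sharing is safe; tests that mutate it work on copies).
test_pack <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- synthetic_pack(42)
    cache
  }
})

# Independent oracle for the odds-ratio -> risk-ratio conversion: build the
# 2x2 table implied by (OR, p0) and read the risk ratio off it directly.
rr_oracle <- function(or, p0) {
  odds0 <- p0 / (1 - p0)
  odds1 <- or * odds0
  p1 <- odds1 / (1 + odds1)
  p1 / p0
}

expect_valid_dist <- function(d) {
  expect_length(d, 3)
  expect_true(all(d >= -1e-12 & d <= 1 + 1e-12))
  expect_equal(sum(d), 1, tolerance = 1e-9)
}
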