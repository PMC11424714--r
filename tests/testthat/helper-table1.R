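# Reference principal-part polynomials of the low-order Laurent table,
# entered by hand as (w_pow, t_pow, coef) triples.  Rows n = 0..4, columns
# m = n+1, n+2, n+3.
table1_reference <- local({
  entry <- function(...) {
    m <- matrix(c(...), ncol = 3, byrow = TRUE)
    data.frame(w_pow = m[, 1], t_pow = m[, 2], coef = m[, 3])
  }
  list(
    # n = 0
    "1_0" = entry(1, 1, 4),
    "2_0" = entry(1, 1, -12,  3, 1, 24,  1, 2, 192),
    "3_0" = entry(1, 1, 24,  3, 1, -120,  5, 1, 120,
                  1, 2, -960,  3, 2, 2880,  1, 3, 23040),
    # n = 1
    "2_1" = entry(3, 1, 8),
    "3_1" = entry(3, 1, -40,  5, 1, 60,  3, 2, 960),
    "4_1" = entry(3, 1, 120,  5, 1, -420,  7, 1, 336,
                  3, 2, -6720,  5, 2, 13440,  3, 3, 215040),
    # n = 2
    "3_2" = entry(5, 1, 12),
    "4_2" = entry(5, 1, -84,  7, 1, 112,  5, 2, 2688),
    "5_2" = entry(5, 1, 336,  7, 1, -1008,  9, 1, 720,
                  5, 2, -24192,  7, 2, 40320,  5, 3, 967680),
    # n = 3
    "4_3" = entry(7, 1, 16),
    "5_3" = entry(7, 1, -144,  9, 1, 180,  7, 2, 5760),
    "6_3" = entry(7, 1, 720,  9, 1, -1980,  11, 1, 1320,
                  7, 2, -63360,  9, 2, 95040,  7, 3, 3041280),
    # n = 4
    "5_4" = entry(9, 1, 20),
    "6_4" = entry(9, 1, -220,  11, 1, 264,  9, 2, 10560),
    "7_4" = entry(9, 1, 1320,  11, 1, -3432,  13, 1, 2184,
                  9, 2, -137280,  11, 2, 192192,  9, 3, 7687680)
  )
})

pp_as_canonical <- function(terms) {
  terms <- terms[order(terms$t_pow, terms$w_pow), , drop = FALSE]
  rownames(terms) <- NULL
  terms
}
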