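# Shared fixtures, built in code.

# Three-subject readings table (device + 3 radiologists, one
# classification).  Per-subject radiologist scores r_i = (1/3, 1, 1/3),
# so the pooled radiologist concordance rate is 5/9; device-radiologist
# scores s_i = (2/3, 1, 2/3).
toy_readings <- function() {
  rows <- list(
    c("p1", "oval", "oval", "oval", "round"),
    c("p2", "oval", "oval", "oval", "oval"),
    c("p3", "round", "round", "irregular", "round")
  )
  do.call(rbind, lapply(rows, function(r) {
    data.frame(
      subject_id = r[1],
      reader_id = c("dev", "rad1", "rad2", "rad3"),
      reader_role = c("device", "radiologist", "radiologist", "radiologist"),
      classification = "Shape",
      value = r[-1],
      stringsAsFactors = FALSE
    )
  }))
}

# concordance_data1 with prescribed per-subject scores via single-column
# blow-up is not possible (scores are means of 0/1); instead build data
# whose r_i / s_i match given vectors with m = 2 where scores are in
# {0, 1/2... }; tests that need exact score vectors construct objects
# directly through the constructor with hand-chosen indicator rows.
data1_from_scores <- function(r_pairs, s_cols) {
  concordance_data1(as.matrix(r_pairs), as.matrix(s_cols))
}

# reference grids of published required sample sizes, indexed by
# (rate block) x (delta, rho) rows and power columns
table1_n <- matrix(
  c(210, 290, 206, 285, 200, 275, 186, 256,
    56, 76, 55, 75, 53, 73, 50, 68,
    249, 344, 245, 338, 237, 327, 220, 304,
    66, 90, 65, 88, 63, 86, 58, 80,
    210, 290, 206, 285, 200, 275, 186, 256,
    56, 76, 55, 75, 53, 73, 50, 68),
  ncol = 2, byrow = TRUE
)

table2_n <- matrix(
  c(348, 465, 328, 438, 298, 397, 245, 327,
    86, 113, 81, 107, 74, 98, 63, 83,
    434, 580, 409, 546, 370, 495, 304, 406,
    111, 148, 105, 140, 96, 127, 79, 105,
    382, 511, 360, 481, 327, 436, 269, 359,
    103, 136, 97, 129, 89, 117, 74, 98),
  ncol = 2, byrow = TRUE
)

design_grid <- function() {
  expand.grid(power = c(0.8, 0.9), rho = c(0.1, 0.3, 0.5, 0.7),
              delta = c(0.05, 0.1), rate = c(0.3, 0.5, 0.7))
}
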