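# loaded once per test run; all fixture-based tests share this
study <- nts_study()
all_candidates <- c(paste0("X", 1:10), paste0("Z", 1:6))
y1_terms <- c("X1", "X9", "X10", "Z5", "Z6")
y2_terms <- c("X1", "Z1", "Z2", "Z4")

# grading-example attribute vector for one batch
example_z <- function(batch_id) {
  ge <- study$grading_examples
  unlist(ge[ge$batch_id == batch_id, c("Z1", "Z2", "Z4", "Z5", "Z6")])
}
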