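# small conveniences for the network tests
clip_intensities_for_test <- function(volume, probs) {
  couinaud3d:::clip_intensities(volume, probs)
}

label_argmax <- function(probs4) {
  d <- dim(probs4)
  array(max.col(matrix(probs4, ncol = d[4]), ties.method = "first") - 1L,
        d[1:3])
}
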