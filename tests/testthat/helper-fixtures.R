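# shared fixtures built in code; kept small so the whole suite stays fast
lib176 <- make_endmember_library()

# independent per-pixel tallying oracle for confusion counts
oracle_confusion <- function(pred, truth, k = 3) {
  m <- matrix(0, k, k)
  for (i in seq_along(pred)) {
    m[truth[i] + 1L, pred[i] + 1L] <- m[truth[i] + 1L, pred[i] + 1L] + 1
  }
  m
}

# independent set-based IoU oracle from raw masks
oracle_iou <- function(pred, truth, cls) {
  inter <- sum(pred == cls & truth == cls)
  uni <- sum(pred == cls | truth == cls)
  if (uni == 0) NA_real_ else inter / uni
}
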