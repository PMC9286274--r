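# Trend assertion over a grid: the total change across the grid must exceed
# k * the combined sem of the end points, with the stated sign, and the
# rank correlation must agree.
expect_trend <- function(x, y, sem, sign = +1, k = 2, label = "trend") {
  total <- (y[length(y)] - y[1]) * sign
  noise <- sqrt(sem[1]^2 + sem[length(sem)]^2)
  expect_gt(total, k * noise, label = sprintf("%s: signed total change", label))
  expect_gt(sign * cor(x, y, method = "spearman"), 0,
            label = sprintf("%s: rank correlation", label))
}
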