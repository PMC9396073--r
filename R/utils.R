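## Round half away from zero (R's round() is banker's rounding).
.roundAway <- function(x, digits = 0L) {
    f <- 10^digits
    sign(x) * floor(abs(x) * f + 0.5) / f
}
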