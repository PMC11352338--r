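# Internal angle helpers. Headings live in (-pi, pi], CCW from +x.

# wrap any angle into (-pi, pi]
.wrapAngle <- function(a) {
  w <- (a + pi) %% (2 * pi) - pi
  # %% maps exact multiples of 2*pi to -pi; convention keeps +pi
  w[w == -pi] <- pi
  w
}

# signed shorter-arc difference a - b in (-pi, pi]; ties (exactly pi apart)
# resolve toward positive rotation
.angDiff <- function(a, b) .wrapAngle(a - b)

# circular linear interpolation from a to b along the shorter arc,
# t in [0, 1]; exact-pi ties go toward positive rotation
.circInterp <- function(a, b, t) {
  .wrapAngle(a + t * .angDiff(b, a))
}

.stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
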