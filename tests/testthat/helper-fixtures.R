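# Random balanced participant x method x session tables with known structure.
randomBalancedStudy <- function(n, methods = c("A", "B", "C"), sessions = 2,
                                methodEffects = NULL, sessionEffect = 0,
                                participantSD = 1, residSD = 0.5,
                                grandMean = 10) {
  if (is.null(methodEffects)) methodEffects <- rep(0, length(methods))
  d <- expand.grid(participant = sprintf("P%02d", seq_len(n)),
                   method = methods, session = seq_len(sessions),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pEff <- stats::rnorm(n, 0, participantSD)
  d$y <- grandMean +
    methodEffects[match(d$method, methods)] +
    sessionEffect * (d$session == 2) +
    pEff[match(d$participant, sprintf("P%02d", seq_len(n)))] +
    stats::rnorm(nrow(d), 0, residSD)
  d
}

# A quantified single-metabolite study table for the comparison helpers.
tinyQuantifiedStudy <- function(n = 4, concByMethod = c(A = 7, B = 8)) {
  methods <- names(concByMethod)
  d <- expand.grid(participant = sprintf("P%02d", seq_len(n)),
                   method = methods, session = 1:2,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d$metabolite <- "tCr"
  d$conc_mM <- concByMethod[d$method]
  d
}
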