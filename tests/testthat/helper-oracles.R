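# Independent oracles used by property-style tests. These deliberately use
# naive, readable algorithms distinct from the package implementations.

# Hand-enumerated haplotype rule table: x is a logical triple
# (AAEL019678, AAEL023844, AAEL005113) of "amplified at/above threshold".
oracleHaplotype <- function(hi) {
    if (!any(hi)) return("negative")
    if (all(hi)) return("A")
    if (hi[1] && hi[2] && !hi[3]) return("B")
    "other"
}

# Brute-force amplified-region caller: walks the track window by window.
# states: "E" eligible, "M" masked, "O" other
oracleRegions <- function(ratioVals, maskedVals, foldMin, minWindows,
                          maxMaskGap) {
    n <- length(ratioVals)
    state <- ifelse(maskedVals, "M",
                    ifelse(ratioVals >= foldMin, "E", "O"))
    regions <- list()
    i <- 1
    while (i <= n) {
        if (state[i] != "E") { i <- i + 1; next }
        members <- i
        j <- i + 1
        while (j <= n) {
            if (state[j] == "E") { members <- c(members, j); j <- j + 1 }
            else if (state[j] == "M") {
                # look ahead over the masked gap
                k <- j
                while (k <= n && state[k] == "M") k <- k + 1
                if (k <= n && state[k] == "E" && (k - j) <= maxMaskGap) {
                    j <- k
                } else break
            } else break
        }
        if (length(members) >= minWindows)
            regions[[length(regions) + 1]] <- list(
                first = members[1], last = members[length(members)],
                fold = median(ratioVals[members]), n = length(members))
        i <- j
    }
    regions
}

# Simple Cq crossing oracle: scan cycle pairs for the first upward crossing.
oracleCq <- function(trace, thr) {
    for (i in 2:length(trace)) {
        if (trace[i - 1] < thr && trace[i] >= thr)
            return((i - 1) + (thr - trace[i - 1]) / (trace[i] - trace[i - 1]))
    }
    NA_real_
}

# Build a small RatioTrack directly from ratio/masked vectors (1-kb windows).
makeRatioTrack <- function(ratioVals, maskedVals, contig = "chrT",
                           window = 1000L) {
    n <- length(ratioVals)
    caseDepth <- ifelse(maskedVals, 0, ratioVals)
    ctrl <- DepthTrack(contig, (seq_len(n) - 1L) * window,
                       seq_len(n) * window,
                       ifelse(maskedVals, 0, 1))
    cs <- DepthTrack(contig, (seq_len(n) - 1L) * window,
                     seq_len(n) * window, caseDepth)
    ratioTrack(cs, ctrl, maskFloor = 0.25)
}
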