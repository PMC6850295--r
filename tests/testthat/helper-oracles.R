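# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (double loops, direct definitions) so they cannot share
# a defect with the vectorised implementation.

# 3x3 max-minus-min with replicate padding, double loop
bruteBeucher <- function(m) {
    nr <- nrow(m); nc <- ncol(m)
    out <- matrix(0, nr, nc)
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
        rs <- pmin(pmax((r - 1):(r + 1), 1), nr)
        cs <- pmin(pmax((c - 1):(c + 1), 1), nc)
        w <- m[rs, cs]
        out[r, c] <- max(w) - min(w)
    }
    out
}

# per-pixel boundary membership: p in phase and some 8-neighbour outside the
# phase (the image frame counts as outside)
brutePhaseBoundary <- function(B) {
    nr <- nrow(B); nc <- ncol(B)
    E <- matrix(FALSE, nr, nc)
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
        if (!B[r, c]) next
        if (r == 1 || r == nr || c == 1 || c == nc) { E[r, c] <- TRUE; next }
        for (dr in -1:1) for (dc in -1:1)
            if (!B[r + dr, c + dc]) E[r, c] <- TRUE
    }
    E
}

# gradient curves by direct looping over levels and pixels
bruteCurve <- function(px, G, polarity = "dark") {
    lev <- min(px):max(px)
    nB <- integer(length(lev)); gT <- numeric(length(lev))
    for (i in seq_along(lev)) {
        B <- if (polarity == "dark") px <= lev[i] else px >= lev[i]
        E <- brutePhaseBoundary(B)
        nB[i] <- sum(E)
        gT[i] <- sum(G[E])
    }
    list(levels = lev, nBoundary = nB, gTotal = gT,
         gAverage = ifelse(nB > 0, gT / pmax(nB, 1), 0))
}

# digital disk: pixels whose centre lies within distance r of the centre
makeDisk <- function(r, n = 2 * r + 5) {
    cx <- (n + 1) / 2
    outer(seq_len(n), seq_len(n),
          function(i, j) (i - cx)^2 + (j - cx)^2 <= r^2)
}

# solid axis-aligned bar as a logical matrix with background margin
makeBar <- function(h, w) {
    m <- matrix(FALSE, h + 2, w + 2)
    m[2:(h + 1), 2:(w + 1)] <- TRUE
    m
}

# one-pixel-wide rectangular ring
makeRing <- function(n, r1, r2, c1, c2) {
    m <- matrix(FALSE, n, n)
    m[r1:r2, c1] <- TRUE; m[r1:r2, c2] <- TRUE
    m[r1, c1:c2] <- TRUE; m[r2, c1:c2] <- TRUE
    m
}

randomGrey <- function(nr, nc, seed, top = 255L) {
    set.seed(seed)
    greyImage(matrix(sample(0:top, nr * nc, replace = TRUE), nr, nc))
}

# GradientCurve from a bare statistic vector (levels 0..n-1, unit boundary)
curveFromStat <- function(values, nBoundary = rep(1L, length(values))) {
    new("GradientCurve", levels = seq_along(values) - 1L,
        nBoundary = as.integer(nBoundary),
        gTotal = values * nBoundary, gAverage = ifelse(nBoundary > 0,
                                                       values, 0),
        polarity = "dark")
}
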