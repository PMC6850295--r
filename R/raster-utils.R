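# Internal raster primitives. All matrices are [row, column]; linear indices
# are column-major as in base R.

# clamped index vector: replicate padding
.clampIdx <- function(n, d) pmin(pmax(seq_len(n) + d, 1L), n)

# shifted view with replicate padding: out[r, c] = m[clamp(r + dr), clamp(c + dc)]
.shiftRep <- function(m, dr, dc)
    m[.clampIdx(nrow(m), dr), .clampIdx(ncol(m), dc), drop = FALSE]

# shifted view with constant padding
.shiftPad <- function(m, dr, dc, pad) {
    nr <- nrow(m); nc <- ncol(m)
    out <- matrix(pad, nr, nc)
    rs <- seq_len(nr) + dr
    cs <- seq_len(nc) + dc
    rok <- rs >= 1L & rs <= nr
    cok <- cs >= 1L & cs <= nc
    if (any(rok) && any(cok))
        out[rok, cok] <- m[rs[rok], cs[cok]]
    out
}

.OFF8 <- cbind(dr = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
               dc = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L))

# 3x3 greyscale dilation / erosion with replicate padding
.localMax3 <- function(m) {
    out <- m
    for (k in seq_len(nrow(.OFF8)))
        out <- pmax(out, .shiftRep(m, .OFF8[k, 1L], .OFF8[k, 2L]))
    out
}

.localMin3 <- function(m) {
    out <- m
    for (k in seq_len(nrow(.OFF8)))
        out <- pmin(out, .shiftRep(m, .OFF8[k, 1L], .OFF8[k, 2L]))
    out
}

# binary erosion by the 3x3 square, outside-image treated as background
.binErode3 <- function(m) {
    out <- m
    for (k in seq_len(nrow(.OFF8)))
        out <- out & .shiftPad(m, .OFF8[k, 1L], .OFF8[k, 2L], FALSE)
    out
}

# 3x3 correlation with replicate padding
.conv3 <- function(m, kern) {
    out <- matrix(0, nrow(m), ncol(m))
    for (i in 1:3) for (j in 1:3) {
        w <- kern[i, j]
        if (w != 0)
            out <- out + w * .shiftRep(m, i - 2L, j - 2L)
    }
    out
}

# separable Gaussian smoothing (sigma = radius), replicate padding
.gaussSmooth <- function(m, sigma) {
    if (sigma <= 0) return(m)
    h <- max(1L, as.integer(ceiling(3 * sigma)))
    w <- stats::dnorm(-h:h, sd = sigma)
    w <- w / sum(w)
    tmp <- matrix(0, nrow(m), ncol(m))
    for (k in -h:h)
        tmp <- tmp + w[k + h + 1L] * .shiftRep(m, k, 0L)
    out <- matrix(0, nrow(m), ncol(m))
    for (k in -h:h)
        out <- out + w[k + h + 1L] * .shiftRep(tmp, 0L, k)
    out
}

# 4-neighbour successors of linear indices, bounds-checked; returns list(from, to)
.neigh4 <- function(idx, nr, nc) {
    rows <- (idx - 1L) %% nr + 1L
    up <- idx[rows > 1L]
    dn <- idx[rows < nr]
    lf <- idx[idx > nr]
    rt <- idx[idx <= nr * (nc - 1L)]
    list(from = c(up, dn, lf, rt),
         to = c(up - 1L, dn + 1L, lf - nr, rt + nr))
}

# 8-neighbour successors of linear indices
.neigh8 <- function(idx, nr, nc) {
    rows <- (idx - 1L) %% nr + 1L
    notTop <- rows > 1L; notBot <- rows < nr
    notLf <- idx > nr; notRt <- idx <= nr * (nc - 1L)
    from <- c(idx[notTop], idx[notBot], idx[notLf], idx[notRt],
              idx[notTop & notLf], idx[notTop & notRt],
              idx[notBot & notLf], idx[notBot & notRt])
    to <- c(idx[notTop] - 1L, idx[notBot] + 1L,
            idx[notLf] - nr, idx[notRt] + nr,
            idx[notTop & notLf] - 1L - nr, idx[notTop & notRt] - 1L + nr,
            idx[notBot & notLf] + 1L - nr, idx[notBot & notRt] + 1L + nr)
    list(from = from, to = to)
}

# pixels of the background 4-connected to the image frame
.floodFromFrame4 <- function(bg) {
    nr <- nrow(bg); nc <- ncol(bg)
    bgv <- as.vector(bg)
    reach <- logical(nr * nc)
    frame <- unique(c(seq_len(nr), seq_len(nr) + nr * (nc - 1L),
                      (seq_len(nc) - 1L) * nr + 1L, seq_len(nc) * nr))
    frontier <- frame[bgv[frame]]
    reach[frontier] <- TRUE
    while (length(frontier)) {
        nb <- .neigh4(frontier, nr, nc)$to
        nb <- unique(nb[bgv[nb] & !reach[nb]])
        reach[nb] <- TRUE
        frontier <- nb
    }
    matrix(reach, nr, nc)
}

# 8-connected component labelling of a logical mask; 0 = background.
# Components are numbered in order of their smallest (column-major) pixel.
.label8 <- function(mask) {
    nr <- nrow(mask); nc <- ncol(mask)
    lab <- matrix(0L, nr, nc)
    idx <- which(mask)
    n <- length(idx)
    if (n == 0L) return(lab)
    vid <- integer(nr * nc)
    vid[idx] <- seq_len(n)
    # forward edges only (each undirected adjacency appears once)
    fwd <- cbind(dr = c(1L, 0L, 1L, -1L), dc = c(0L, 1L, 1L, 1L))
    ef <- integer(0); et <- integer(0)
    for (k in seq_len(nrow(fwd))) {
        dr <- fwd[k, 1L]; dc <- fwd[k, 2L]
        both <- mask & .shiftPad(mask, dr, dc, FALSE)
        w <- which(both)
        if (length(w)) {
            ef <- c(ef, w)
            et <- c(et, w + dr + dc * nr)
        }
    }
    if (length(ef)) {
        g <- igraph::make_empty_graph(n = n, directed = FALSE)
        g <- igraph::add_edges(g, rbind(vid[ef], vid[et]))
        memb <- igraph::components(g)$membership
    } else {
        memb <- seq_len(n)
    }
    # renumber components by first occurrence (column-major order of idx)
    memb <- match(memb, unique(memb))
    lab[idx] <- memb
    lab
}

# bounding box (rmin, rmax, cmin, cmax) of TRUE pixels
.bbox <- function(mask) {
    w <- which(mask, arr.ind = TRUE)
    c(min(w[, 1L]), max(w[, 1L]), min(w[, 2L]), max(w[, 2L]))
}
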