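# internal helpers shared across modules

# run code with a temporary RNG state seeded from `seed`
.withSeed <- function(seed, code) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    force(code)
}

# stable 31-bit hash of identity components, for derived sub-seeds:
# adding a replicate/fov never perturbs the streams of existing ones
.stableSeed <- function(...) {
    s <- paste(vapply(list(...), as.character, ""), collapse = "/")
    h <- 0
    for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483629
    as.integer(h)
}

# 8-connected labeling of a logical matrix by row-run union-find.
# Returns an integer matrix, 0 = background, labels 1..k.
.label8 <- function(mask) {
    n <- nrow(mask); p <- ncol(mask)
    out <- matrix(0L, n, p)
    if (!any(mask)) return(out)
    parent <- integer(0)
    nlab <- 0L
    find <- function(i) {
        while (parent[i] != i) i <- parent[i]
        i
    }
    maxRuns <- sum(mask) %/% 1L  # upper bound; trimmed later
    runRow <- integer(maxRuns); runStart <- integer(maxRuns)
    runEnd <- integer(maxRuns); runLab <- integer(maxRuns)
    nRuns <- 0L
    prevIdx <- integer(0)
    for (i in seq_len(n)) {
        rowv <- mask[i, ]
        if (!any(rowv)) { prevIdx <- integer(0); next }
        r <- rle(rowv)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        starts <- starts[r$values]; ends <- ends[r$values]
        curIdx <- integer(length(starts))
        for (k in seq_along(starts)) {
            lab <- 0L
            for (o in prevIdx) {
                # 8-connectivity: previous-row run overlapping [start-1, end+1]
                if (runStart[o] <= ends[k] + 1L &&
                    runEnd[o] >= starts[k] - 1L) {
                    root <- find(runLab[o])
                    if (lab == 0L) {
                        lab <- root
                    } else if (root != lab) {
                        if (root < lab) { parent[lab] <- root; lab <- root }
                        else parent[root] <- lab
                    }
                }
            }
            if (lab == 0L) {
                nlab <- nlab + 1L
                parent[nlab] <- nlab
                lab <- nlab
            }
            nRuns <- nRuns + 1L
            runRow[nRuns] <- i; runStart[nRuns] <- starts[k]
            runEnd[nRuns] <- ends[k]; runLab[nRuns] <- lab
            curIdx[k] <- nRuns
        }
        prevIdx <- curIdx
    }
    roots <- vapply(seq_len(nlab), find, 0L)
    compact <- integer(nlab)
    compact[sort(unique(roots))] <- seq_along(unique(roots))
    for (q in seq_len(nRuns)) {
        out[runRow[q], runStart[q]:runEnd[q]] <-
            compact[roots[runLab[q]]]
    }
    out
}

# component sizes of a label matrix (named by label)
.labelSizes <- function(lab) {
    mx <- max(lab)
    if (mx == 0L) return(integer(0))
    tabulate(lab[lab > 0L], nbins = mx)
}

# binary morphology wrappers (EBImage); masks in/out as logical matrices
.dilateBox <- function(mask, r) {
    if (r < 1L || !any(mask)) return(mask)
    k <- EBImage::makeBrush(2L * r + 1L, shape = "box")
    EBImage::dilate(mask + 0, k) > 0.5
}

.dilateDisc <- function(mask, r) {
    if (r < 1L || !any(mask)) return(mask)
    k <- EBImage::makeBrush(2L * r + 1L, shape = "disc")
    EBImage::dilate(mask + 0, k) > 0.5
}

.erodeBox <- function(mask, r) {
    if (r < 1L || !any(mask)) return(mask)
    k <- EBImage::makeBrush(2L * r + 1L, shape = "box")
    EBImage::erode(mask + 0, k) > 0.5
}

.closeDisc <- function(mask, r) {
    if (r < 1L || !any(mask)) return(mask)
    k <- EBImage::makeBrush(2L * r + 1L, shape = "disc")
    EBImage::closing(mask + 0, k) > 0.5
}

.fillHoles <- function(mask) {
    if (!any(mask)) return(mask)
    EBImage::fillHull(mask + 0) > 0.5
}
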