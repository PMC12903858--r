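## Internal helpers.

## Evaluate expr under set.seed(seed) without disturbing the caller's RNG
## stream; seed = NULL uses the current stream.
.withSeed <- function(seed, expr) {
    if (is.null(seed)) return(eval.parent(substitute(expr)))
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    eval.parent(substitute(expr))
}

## sin(x)/x with the x -> 0 limit.
.sinc <- function(x) ifelse(x == 0, 1, sin(x) / x)

## Deterministic quasi-uniform directions on the unit sphere.
.fibonacciSphere <- function(n) {
    i <- seq_len(n) - 0.5
    z <- 1 - 2 * i / n
    r <- sqrt(pmax(0, 1 - z^2))
    phi <- pi * (1 + sqrt(5)) * i
    cbind(r * cos(phi), r * sin(phi), z)
}

.randomSphere <- function(n) {
    z <- stats::runif(n, -1, 1)
    phi <- stats::runif(n, 0, 2 * pi)
    r <- sqrt(pmax(0, 1 - z^2))
    cbind(r * cos(phi), r * sin(phi), z)
}
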