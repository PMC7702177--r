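# Shared fixtures: everything is generated in code; no binary files.

FROZEN_NOW <- "2020-06-01T12:00:00Z"

with_frozen_clock <- function(code) {
  withr::with_options(list(bcokit.now = FROZEN_NOW), code)
}

demo_meta <- function(name = "demo object") {
  author_metadata(
    provenance = list(
      name = name,
      version = "2.1",
      contributors = list(
        list(name = "Ada Author", contribution = list("authoredBy")),
        list(name = "Rex Reviewer", contribution = list("createdBy"))
      )
    ),
    usability = c("documents a synthetic analysis", "for tests only")
  )
}

demo_workflow <- function(n_steps = 3L, n_inputs = 2L, n_outputs = 1L,
                          wiring = "chain", seed = 11L) {
  parse_cwl(generate_cwl(generator_spec(
    n_inputs = n_inputs, n_outputs = n_outputs, n_steps = n_steps,
    wiring = wiring, seed = seed)))
}

demo_bco <- function(...) {
  with_frozen_clock(compose_from_cwl(demo_workflow(...), demo_meta()))
}

rnaseq_fixture_path <- function() {
  system.file("extdata", "rnaseq-de-pathway-synthetic.cwl.json",
              package = "bcokit")
}

# recursively shuffle object key order (seeded) without changing content
shuffle_keys <- function(x, seed) {
  set.seed(seed)
  shuf <- function(v) {
    if (!is.list(v)) return(v)
    if (is.null(names(v)) || !any(nzchar(names(v)))) {
      out <- lapply(v, shuf)
      attributes(out) <- attributes(v)
      return(out)
    }
    ord <- sample(length(v))
    out <- lapply(v[ord], shuf)
    attributes(out)$names <- names(v)[ord]
    class(out) <- class(v)
    out
  }
  shuf(x)
}

# random small JSON-like tree for property tests
random_tree <- function(seed, depth = 3L) {
  set.seed(seed)
  gen <- function(d) {
    if (d == 0L || runif(1) < 0.3) {
      return(switch(sample.int(4L, 1L),
                    paste0("s", sample.int(100L, 1L)),
                    sample.int(1000L, 1L),
                    runif(1),
                    sample(c(TRUE, FALSE), 1L)))
    }
    n <- sample.int(4L, 1L)
    if (runif(1) < 0.5) {
      structure(lapply(seq_len(n), function(i) gen(d - 1L)),
                names = paste0("k", sample(100L, n)))
    } else {
      structure(lapply(seq_len(n), function(i) gen(d - 1L)),
                class = "json_arr")
    }
  }
  gen(depth)
}
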