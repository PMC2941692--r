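# Shared fixtures: all inputs are generated in code at test time.

# A compact model with several giant loops: 20 kbp chromosome, 6 kbp walk
# steps, 60 kbp loops scaled down together so loop structure is exercised.
small_model <- function(len = 2e4, seed = 5, ...) {
  g <- synth_genome(lengths = len, seed = seed)
  build_genome_model(
    g, seed = seed,
    nuclear = nuclear_params(loop_size_bp = 6e4, step_bp = 6e3,
                             step_length_nm = 150,
                             nucleus_radius_nm = 2000),
    ...
  )
}

# A 2 kbp toy chromosome (10 nucleosome repeats) with walk scales shrunk
# proportionally so every scale still exists.
tiny_model <- function(len = 2000, seed = 5, ...) {
  g <- synth_genome(lengths = len, seed = seed)
  build_genome_model(
    g, seed = seed,
    nuclear = nuclear_params(loop_size_bp = 4000, step_bp = 1000,
                             step_length_nm = 100,
                             nucleus_radius_nm = 1500),
    bp_per_point = 200,
    ...
  )
}

frame_cols <- function() {
  c("x", "y", "z",
    "e1x", "e1y", "e1z", "e2x", "e2y", "e2z", "e3x", "e3y", "e3z")
}

frame_origin <- function(frames, i) {
  as.numeric(frames[i, c("x", "y", "z")])
}

frame_axis <- function(frames, i, axis = "e1") {
  as.numeric(frames[i, paste0(axis, c("x", "y", "z"))])
}

# A deliberately tilted, rotated frame for exercising geometry away from
# the identity orientation.
tilted_frame <- function() {
  e3 <- c(1, 2, 2) / 3
  e1 <- c(2, -2, 1) / 3
  e2 <- c(e3[2] * e1[3] - e3[3] * e1[2],
          e3[3] * e1[1] - e3[1] * e1[3],
          e3[1] * e1[2] - e3[2] * e1[1])
  frame(origin = c(10, -4, 7), e1 = e1, e2 = e2, e3 = e3)
}

point_radii <- function(path) {
  sqrt(path$x^2 + path$y^2 + path$z^2)
}
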