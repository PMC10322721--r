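# Shared fixtures, built once per test run.

# medium cortex used across modules (60 areas, 2562 vertices)
tc60 <- local({
  cx <- NULL
  function() {
    if (is.null(cx)) cx <<- generate_toy_cortex(60, 4, seed = 2)
    cx
  }
})

# small cortex for cheap geometry tests (8 areas, 162 vertices)
tc8 <- local({
  cx <- NULL
  function() {
    if (is.null(cx)) cx <<- generate_toy_cortex(8, 2, seed = 1)
    cx
  }
})

std_ligand <- function() ligand_params(E = 0.5, B = 10, S_a = 5, K_D = 1, L = 1)

# concave, monotone-decreasing film response standards
std_standards <- function() {
  data.frame(gray = c(20, 60, 110, 160, 210, 250),
             R = c(900, 600, 380, 220, 100, 30),
             W_b = 2)
}
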