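Package: blochvm
Title: Multi-Lane Stack Virtual Machine with a Dynamic Bloch-Equation MRI Simulator
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: A Turing-complete, stack-based bytecode virtual machine that
    emulates SIMT (GPU-thread-style) execution over parallel lanes with
    per-lane stacks and heaps, shared typed environment buffers and barrier
    synchronization; a small C-like language and compiler (recursive-descent
    parser, semantic analysis with overload dispatch, VALUE/OP instruction
    fusion); benchmark programs (Rule 110 cellular automaton, Mandelbrot
    escape-time) with independent oracles; and a Strang-split Bloch-equation
    SPGR CINE simulator on synthetic digital phantoms whose T1 and
    off-resonance maps are recomputed at run time - natively or by routines
    executing on the virtual machine - for contrast-agent diffusion and
    proton-resonance-frequency shift thermometry.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    pracma,
    png,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
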