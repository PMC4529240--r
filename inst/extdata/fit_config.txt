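# maximum-likelihood fit settings for the cohort analysis
seed = 7
restarts = 2          # simplex starts per fit (first is data-driven)
quad_nodes = 12       # Gauss-Legendre nodes for the threshold integral
maxit = 400           # simplex iterations per start
polish_maxit = 600    # iterations per polish round
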