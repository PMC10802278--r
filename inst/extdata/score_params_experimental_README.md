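# Transcribing the experimental (mu, sigma) score table

The experimentally derived means and standard deviations of the five
crossbridge fiducial distances come from a multibody-refinement
analysis of crossbridge particles; they are not redistributed with
this package.

To enable `synth_score_params(mode = "experimental")`, transcribe the five
(mu, sigma) pairs into `inst/extdata/score_params_experimental.csv` with the
layout below (units: nm, rows ordered d1..d5) and reinstall:

    # provenance: <where the numbers were transcribed from, with date>
    distance,mu,sigma
    d1,<mu1>,<sigma1>
    d2,<mu2>,<sigma2>
    d3,<mu3>,<sigma3>
    d4,<mu4>,<sigma4>
    d5,<mu5>,<sigma5>

Until then, every quantitative analysis in the package runs under the
self-consistent `"idealized"` set (see `?synth_score_params`), and the
checks that depend specifically on the experimental table are reported
as unavailable rather than silently substituted.
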