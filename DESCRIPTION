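Package: sedrl
Title: Reinforcement-Learning Sedation Dosing from Logged ICU Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Learns patient-specific joint propofol and fentanyl dosing
    policies from logged hourly intensive-care trajectories using an
    off-policy deep deterministic policy gradient (DDPG) agent with
    prioritized experience replay. Provides the full analysis pipeline:
    hourly windowing, sample-and-hold imputation and z-normalization of
    14-feature state vectors; a sigmoid band reward keeping the Riker
    Sedation-Agitation Scale (SAS, band 3-4) and mean arterial pressure
    (MAP, band 65-85 mmHg) in their therapeutic ranges while penalizing
    total dose; a learned next-state dynamics model for counterfactual
    rollouts; performance-error statistics (PE, MDPE, MPE, RMSE) with
    Welch t-tests comparing the learned policy against the logged
    clinician behavior policy; and a synthetic patient-cohort generator
    with heterogeneous drug sensitivity for end-to-end testing without
    protected clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
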