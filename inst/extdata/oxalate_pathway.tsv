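# Three-step heterologous oxalate pathway to glyoxylate (the glycolic acid
# precursor): oxaloacetase splits oxaloacetate into oxalate and acetate,
# oxalyl-CoA synthetase activates oxalate at the cost of ATP, and
# oxalyl-CoA reductase reduces oxalyl-CoA to glyoxylate with NADPH.
# Metabolite ids are generic; map them to the host model's namespace
# (compartmented ids) before use with a genome-scale model.
reaction_id	equation	lb	ub
OXALOACETASE	oxaloacetate -> oxalate + acetate	0	1000
OXALYLCOA_SYNTHETASE	oxalate + ATP + CoA -> oxalylCoA + AMP + PPi	0	1000
OXALYLCOA_REDUCTASE	oxalylCoA + NADPH -> glyoxylate + CoA + NADP	0	1000
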