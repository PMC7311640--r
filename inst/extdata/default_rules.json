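[{"name":["nadh_site_232"],"ref_positions":[232],"bf_allowed":["A","E"],"nonbf_allowed":["T","S"],"motif":[false]},{"name":["nadh_site_234"],"ref_positions":[234],"bf_allowed":["M"],"nonbf_allowed":["K","S","A"],"motif":[false]},{"name":["fmn_site_367"],"ref_positions":[367],"bf_allowed":["F"],"nonbf_allowed":["Y"],"motif":[false]},{"name":["slbb_427_431"],"ref_positions":[427,428,429,430,431],"bf_allowed":["GGPSG"],"nonbf_allowed":["*"],"motif":[true]}]
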