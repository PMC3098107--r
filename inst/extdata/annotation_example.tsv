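gene_id	category
AT1G01010	housekeeping
AT1G01020	housekeeping
AT1G01020	transport
AT1G01030	response to stress
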