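trigger	kind	scope	window
niet	negation	forward	sentence
geen	negation	forward	sentence
nooit	negation	forward	sentence
zonder	negation	forward	sentence
als	hypothetical	forward	sentence
mogelijk	hypothetical	forward	sentence
misschien	hypothetical	forward	sentence
wellicht	hypothetical	forward	sentence
moeder	non-patient-experiencer	forward	sentence
vader	non-patient-experiencer	forward	sentence
zus	non-patient-experiencer	forward	sentence
broer	non-patient-experiencer	forward	sentence
familie	non-patient-experiencer	forward	sentence
echtgenoot	non-patient-experiencer	forward	sentence
jaren geleden	non-current	forward	sentence
voorheen	non-current	forward	sentence
eerder	non-current	forward	sentence
vroeger	non-current	forward	sentence
in het verleden	non-current	forward	sentence
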