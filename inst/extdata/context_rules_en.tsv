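trigger	kind	scope	window
not	negation	forward	sentence
no	negation	forward	sentence
never	negation	forward	sentence
without	negation	forward	sentence
denies	negation	forward	sentence
if	hypothetical	forward	sentence
possibly	hypothetical	forward	sentence
might	hypothetical	forward	sentence
consider	hypothetical	forward	sentence
unless	hypothetical	forward	sentence
mother	non-patient-experiencer	forward	sentence
father	non-patient-experiencer	forward	sentence
sister	non-patient-experiencer	forward	sentence
brother	non-patient-experiencer	forward	sentence
wife	non-patient-experiencer	forward	sentence
husband	non-patient-experiencer	forward	sentence
daughter	non-patient-experiencer	forward	sentence
son	non-patient-experiencer	forward	sentence
family	non-patient-experiencer	forward	sentence
years ago	non-current	forward	sentence
previously	non-current	forward	sentence
formerly	non-current	forward	sentence
in the past	non-current	forward	sentence
history of	non-current	forward	sentence
last year	non-current	forward	sentence
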