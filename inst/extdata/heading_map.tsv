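BACKGROUND	Background
INTRODUCTION	Background
CONTEXT	Background
OBJECTIVE	Objective
OBJECTIVES	Objective
AIM	Objective
AIMS	Objective
PURPOSE	Objective
GOAL	Objective
METHOD	Methods
METHODS	Methods
DESIGN	Methods
MATERIALS AND METHODS	Methods
STUDY DESIGN	Methods
RESULT	Results
RESULTS	Results
FINDINGS	Results
CONCLUSION	Conclusions
CONCLUSIONS	Conclusions
INTERPRETATION	Conclusions
SUMMARY	Conclusions
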