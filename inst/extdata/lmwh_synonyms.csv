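generic,synonym
enoxaparin,enoxaparin
enoxaparin,enoxaparin sodium
enoxaparin,lovenox
enoxaparin,clexane
enoxaparin,klexane
enoxaparin,inhixa
nadroparin,nadroparin
nadroparin,nadroparin calcium
nadroparin,fraxiparine
nadroparin,fraxiparin
nadroparin,fraxodi
dalteparin,dalteparin
dalteparin,dalteparin sodium
dalteparin,fragmin
tinzaparin,tinzaparin
tinzaparin,tinzaparin sodium
tinzaparin,innohep
tinzaparin,logiparin
bemiparin,bemiparin
bemiparin,bemiparin sodium
bemiparin,zibor
bemiparin,hibor
reviparin,reviparin
reviparin,reviparin sodium
reviparin,clivarin
reviparin,clivarine
parnaparin,parnaparin
parnaparin,parnaparin sodium
parnaparin,fluxum
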