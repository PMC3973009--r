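# Undesirable words: dictionary items too general or too frequent in sense
# definitions to be useful topics. They are removed from item lists (never
# from documents). Extend freely, one word per line; '#' starts a comment.
thing
person
time
agency
cause
object
used
made
make
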