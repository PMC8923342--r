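contraction	expansion
can't	can not
won't	will not
shan't	shall not
i'm	i am
i've	i have
i'll	i will
i'd	i would
you're	you are
you've	you have
you'll	you will
you'd	you would
he's	he is
he'll	he will
he'd	he would
she's	she is
she'll	she will
she'd	she would
it's	it is
it'll	it will
we're	we are
we've	we have
we'll	we will
we'd	we would
they're	they are
they've	they have
they'll	they will
they'd	they would
isn't	is not
aren't	are not
wasn't	was not
weren't	were not
don't	do not
doesn't	does not
didn't	did not
hasn't	has not
haven't	have not
hadn't	had not
couldn't	could not
shouldn't	should not
wouldn't	would not
mustn't	must not
let's	let us
that's	that is
there's	there is
what's	what is
who's	who is
ain't	am not
y'all	you all
'cause	because
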