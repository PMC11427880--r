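contraction	head
what's	what
what're	what
what'd	what
what'll	what
who's	who
who're	who
who'd	who
who'll	who
whose's	whose
where's	where
where'd	where
where'll	where
when's	when
when'd	when
which's	which
why's	why
why'd	why
how's	how
how'd	how
how'll	how
it's	it
that's	that
there's	there
here's	here
i'm	i
i've	i
i'd	i
i'll	i
you're	you
you've	you
you'd	you
you'll	you
he's	he
he'd	he
he'll	he
she's	she
she'd	she
she'll	she
we're	we
we've	we
we'd	we
we'll	we
they're	they
they've	they
they'd	they
they'll	they
isn't	is
aren't	are
wasn't	was
weren't	were
don't	do
doesn't	does
didn't	did
can't	can
couldn't	could
won't	will
wouldn't	would
shouldn't	should
haven't	have
hasn't	has
hadn't	had
let's	let
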